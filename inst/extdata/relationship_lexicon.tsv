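# word	category
husband	spouse
wife	spouse
spouse	spouse
partner	spouse
son	children
daughter	children
child	children
children	children
kid	children
stepson	children
stepdaughter	children
grandson	grandchildren
granddaughter	grandchildren
grandchild	grandchildren
grandchildren	grandchildren
grandkid	grandchildren
greatgrandchild	grandchildren
brother	sibling
sister	sibling
sibling	sibling
mother	parent
father	parent
mom	parent
dad	parent
parent	parent
friend	friend
girlfriend	friend
boyfriend	friend
buddy	friend
pal	friend
neighbor	friend
roommate	friend
niece	other-family
nephew	other-family
cousin	other-family
aunt	other-family
uncle	other-family
inlaw	other-family
family	other-family
relative	other-family
doctor	professional
nurse	professional
caregiver	professional
therapist	professional
pastor	professional
rabbi	professional
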