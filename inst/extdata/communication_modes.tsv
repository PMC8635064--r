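# phrase	mode
phone	phone
call	phone
calls	phone
telephone	phone
email	email
emails	email
e-mail	email
facebook	social media
instagram	social media
social media	social media
online	social media
in person	in person
visit	in person
visits	in person
lunch	in person
dinner	in person
zoom	video
skype	video
facetime	video
video chat	video
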