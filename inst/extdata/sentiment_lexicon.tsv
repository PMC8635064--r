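# token	valence  (packaged default valence lexicon, range about -4..4)
love	3.2
loved	2.9
loves	2.7
loving	2.9
wonderful	2.7
great	3.1
happy	2.7
happiness	2.6
joy	2.8
enjoy	2.2
enjoyed	2.3
fun	2.3
good	1.9
nice	1.8
best	3.2
better	1.9
kind	2.4
warm	1.6
caring	2.2
care	2.0
cared	2.1
supportive	2.0
support	1.7
helpful	1.9
help	1.7
helps	1.6
grateful	2.6
thankful	2.4
blessed	2.9
close	1.3
dear	1.6
special	1.7
meaningful	1.9
comfort	1.8
comfortable	1.5
laugh	2.2
laughing	2.3
smile	2.1
cherish	2.6
treasure	2.3
precious	2.5
proud	2.1
glad	2.0
pleasant	1.9
friendly	2.0
sweet	2.0
trust	1.9
safe	1.4
peaceful	2.0
lucky	1.9
fortunate	2.1
appreciate	2.0
delightful	2.8
amazing	2.8
fine	0.8
okay	0.9
well	1.1
active	0.8
interested	1.4
interesting	1.7
sad	-2.1
sadly	-2.0
lonely	-2.3
loneliness	-2.3
alone	-1.2
isolated	-1.9
lost	-1.3
miss	-1.4
missed	-1.3
hard	-0.4
difficult	-1.5
struggle	-1.9
struggling	-2.0
tired	-1.2
worried	-1.9
worry	-1.8
worries	-1.7
afraid	-2.0
fear	-2.2
scared	-2.0
anxious	-1.9
stress	-1.9
stressful	-2.0
upset	-1.9
angry	-2.3
hurt	-2.0
hurts	-1.9
pain	-2.1
painful	-2.3
cry	-2.0
cried	-2.1
grief	-2.7
grieving	-2.6
died	-2.4
death	-2.6
sick	-1.8
illness	-1.9
empty	-1.3
depressed	-2.7
depressing	-2.4
unhappy	-2.2
terrible	-2.7
awful	-2.6
horrible	-2.8
bad	-2.0
worse	-2.1
worst	-3.1
hate	-2.7
annoyed	-1.7
annoying	-1.8
bother	-1.2
bothers	-1.2
ignore	-1.4
ignored	-1.7
forgotten	-1.8
distant	-1.0
disconnected	-1.5
abandoned	-2.4
burden	-1.8
regret	-2.0
trouble	-1.6
problem	-1.5
problems	-1.6
complain	-1.4
complains	-1.4
argue	-1.7
argument	-1.8
demands	-1.0
demanding	-1.4
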