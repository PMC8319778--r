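%
1	i
2	we
3	posemo
4	negemo
5	sadness
6	body
7	health
8	sexual
9	ingestion
%
afraid	4
alcohol	9
amazing	3
anger	4
angry	4
anguish	4
anxiety	4
anxious	4
appetite	9
arm	6
ashamed	4
ate	9
attracted	8
attraction	8
awful	4
bad	4
beer	9
best	3
better	3
blood	6
body	6
bones	6
brain	6
breakfast	9
calm	3
chest	6
clinic	7
coffee	9
comfort	3
cried	5
cry	4	5
crying	4	5
depressed	4	5
depressing	5
depression	4
diagnosis	7
diet	9
dinner	9
doctor	7
doctors	7
down	5
drank	9
drink	9
drinking	9
eat	9
eating	9
empty	5
enjoy	3
enjoyed	3
excited	3
face	6
fatigue	7
fear	4
flu	7
food	9
fun	3
glad	3
gloomy	5
good	3
grateful	3
great	3
grief	4	5
grieving	5
guilt	4
guilty	4
hand	6
hands	6
happiness	3
happy	3
hate	4
hated	4
head	6
headache	7
headaches	7
health	7
healthy	7
heart	6
heartbroken	5
hope	3
hopeful	3
hopeless	4	5
hospital	7
hunger	9
hungry	9
hurt	4
i	1
i'd	1
i'll	1
i'm	1
i've	1
ill	7
illness	7
im	1
insomnia	7
intimacy	8
intimate	8
joy	3
laugh	3
laughed	3
leg	6
legs	6
let's	2
lets	2
libido	8
loneliness	5
lonely	4	5
love	3
loved	3
low	5
lunch	9
me	1
meal	9
meals	9
medication	7
meds	7
mine	1
miserable	4	5
muscle	6
muscles	6
my	1
myself	1
nausea	7
neck	6
nice	3
numb	4
nurse	7
our	2
ours	2
ourselves	2
pain	7
panic	4
positive	3
proud	3
relieved	3
sad	4	5
sadness	5
scared	4
sex	8
sexual	8
sexuality	8
shame	4
shoulders	6
sick	7
skin	6
smile	3
snack	9
snacking	9
stomach	6
stress	4
stressed	4
symptom	7
symptoms	7
tearful	5
tears	5
terrible	4
therapist	7
therapy	7
upset	4
us	2
we	2
we'd	2
we'll	2
we're	2
we've	2
wine	9
wonderful	3
worried	4
worry	4
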