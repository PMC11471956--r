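dataset	n_contrasts	total_foci	max_foci
Social processing	599	4934	47
PTSD	22	154	26
Substance use	89	657	110
Dementia	28	1194	548
Cue reactivity	275	3197	58
Emotion regulation	338	3543	87
Decision making	145	1225	49
Reward	850	6791	59
Sleep deprivation	44	454	59
Naturalistic	122	1220	59
Problem solving	282	3043	44
Emotion	1738	22038	203
Cannabis use	81	314	16
Nicotine use	13	77	23
Frontal pole CBP	795	9525	57
Face perception	385	2920	50
Nicotine administration	75	349	24
Executive function	243	2629	54
Finger tapping	76	696	27
n-Back	29	640	69
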