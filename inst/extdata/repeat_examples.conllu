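# sent_id = ec_a
1	patient	patient	NOUN	_	_	2	nsubj	_	_
2	suffered	suffer	VERB	_	_	0	root	_	_
3	infarction	infarction	NOUN	_	_	2	obj	_	_
4	myocardial	myocardial	ADJ	_	_	3	amod	_	_

# sent_id = ec_b
1	confirmed	confirm	VERB	_	_	0	root	_	_
2	infarction	infarction	NOUN	_	_	1	obj	_	_
3	myocardial	myocardial	ADJ	_	_	2	amod	_	_
4	second	second	ADJ	_	_	3	amod	_	_

# sent_id = ds_a
1	therapist	therapist	NOUN	_	_	2	nsubj	_	_
2	assigned	assigned	VERB	_	_	0	root	_	_
3	diagnosis	diagnosis	NOUN	_	_	2	obj	_	_
4	diabetes	diabetes	NOUN	_	_	3	nmod	_	_
5	mellitus	mellitus	ADJ	_	_	4	amod	_	_

# sent_id = ds_b
1	cardiologist	cardiologist	NOUN	_	_	2	nsubj	_	_
2	assigned	assigned	VERB	_	_	0	root	_	_
3	diagnosis	diagnosis	NOUN	_	_	2	obj	_	_
4	diabetes	diabetes	NOUN	_	_	3	nmod	_	_
5	mellitus	mellitus	ADJ	_	_	4	amod	_	_
6	ii	ii	NUM	_	_	5	nummod	_	_
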