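keyword	factor	subcategory	equivalents
kindness	service	f1	kindly
courteous	service	f2	
attentive	service	f3	
faithful reply	service	f4	
professional	professionalism	f5	
specialist	professionalism	f6	
professor	professionalism	f7	
skilled	professionalism	f8	
side effects	professionalism	f9	
quick recovery	professionalism	f10	
inpatient	professionalism	f11	
accurate diagnosis	professionalism	f12	
antibiotics	professionalism	f13	
prescription	professionalism	f14	
long term	process	f15	waiting time
right now	process	f16	
medical cost	process	f17	
reception	process	f18	
basic care	process	f19	
parking	environment	f20	
reservation	environment	f21	
waiting room	environment	f22	
office hours	environment	f23	
cleanliness	environment	f24	spotless
sanitary	environment	f25	
mri scanner	environment	f26	
surgery	environment	f27	
spacious ward	environment	f28	
university hospital	environment	f29	
atmosphere	impression	e1	
trustworthy	impression	e2	
first visit	impression	e3	
tired of	impression	e4	
gentle manner	impression	e5	
famous	popularity	e6	renowned
reputation	popularity	e7	
advertised	popularity	e8	
well known	popularity	e9	
word of mouth	popularity	e10	
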