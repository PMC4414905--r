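canonical_id	canonical_name	region	aliases
H01	Saint Mary Pediatric Hospital	Seoul	saint mary|smp hospital
H02	Hangang Children Clinic	Seoul	hangang clinic|hangang children
H03	Dalseong Kids Medical Center	Daegu	dalseong kids|dalseong center
H04	Palgong Child Hospital	Daegu	palgong child|palgong hospital
H05	Haeundae Baby Clinic	Busan	haeundae baby|haeundae clinic
H06	Gwangan Pediatric Center	Busan	gwangan center|gwangan pediatric
H07	Yuseong Child Wellness Hospital	Daejeon	yuseong child|yuseong wellness
H08	Expo Kids Clinic	Daejeon	expo kids|expo clinic
H09	Songdo Child Health Center	Incheon	songdo child|songdo health
H10	Bupyeong Baby Hospital	Incheon	bupyeong baby|bupyeong hospital
H11	Mudeung Children Hospital	Gwangju	mudeung children|mudeung hospital
H12	Chonnam Kids Clinic	Gwangju	chonnam kids|chonnam clinic
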