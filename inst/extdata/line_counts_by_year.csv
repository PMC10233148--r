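trait,year,n_ep,n_nir
b_star,2012,29,29
b_star,2013,188,80
b_star,2014,169,92
b_star,2015,219,114
b_star,2016,161,249
b_star,2017,166,439
b_star,2018,308,8375
b_star,2019,401,17653
Wab,2012,29,29
Wab,2013,189,80
Wab,2014,169,86
Wab,2015,223,114
Wab,2016,161,249
Wab,2017,164,439
Wab,2018,308,8375
Wab,2019,352,17653
PSI,2012,29,29
PSI,2013,189,80
PSI,2014,169,86
PSI,2015,177,114
PSI,2016,194,249
PSI,2017,304,439
PSI,2018,233,8375
PSI,2019,469,17651
FlrYld,2012,28,29
FlrYld,2013,189,80
FlrYld,2014,169,86
FlrYld,2015,251,114
FlrYld,2016,209,249
FlrYld,2017,309,439
FlrYld,2018,379,8374
FlrYld,2019,400,17653
Protein,2012,18,29
Protein,2013,189,80
Protein,2014,169,86
Protein,2015,219,114
Protein,2016,156,249
Protein,2017,114,439
Protein,2018,308,8375
Protein,2019,407,17653
FSV,2012,29,16
FSV,2013,188,5
FSV,2014,166,84
FSV,2015,147,114
FSV,2016,155,249
FSV,2017,131,439
FSV,2018,302,8358
FSV,2019,284,17653
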