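id,sire,dam,sex,birth_date,breed,alive
A_0_1,,,female,1961-07-01,A,TRUE
A_0_2,,,male,1961-07-01,A,TRUE
A_0_3,,,female,1960-07-01,A,FALSE
A_0_4,,,female,1961-07-01,A,FALSE
A_0_5,,,male,1960-07-01,A,FALSE
A_0_6,,,female,1960-07-01,A,FALSE
B_0_1,,,female,1960-07-01,B,TRUE
B_0_2,,,female,1961-07-01,B,FALSE
B_0_3,,,male,1959-07-01,B,FALSE
B_0_4,,,female,1960-07-01,B,FALSE
B_0_5,,,male,1960-07-01,B,TRUE
B_0_6,,,male,1960-07-01,B,TRUE
A_1_1,A_0_2,A_0_3,male,1967-07-01,A,TRUE
A_1_2,A_0_5,A_0_3,female,1967-07-01,A,FALSE
A_1_3,A_0_5,A_0_4,male,1969-07-01,A,FALSE
A_1_4,A_0_2,A_0_4,female,1968-07-01,A,TRUE
A_1_5,A_0_2,A_0_1,female,1968-07-01,A,TRUE
A_1_6,A_0_5,A_0_1,female,1968-07-01,A,TRUE
B_1_1,B_0_6,B_0_4,male,1967-07-01,B,TRUE
B_1_2,B_0_5,B_0_1,male,1967-07-01,B,TRUE
B_1_3,B_0_6,B_0_1,male,1968-07-01,B,TRUE
B_1_4,B_0_6,B_0_4,male,1969-07-01,B,FALSE
B_1_5,B_0_5,B_0_1,female,1969-07-01,B,FALSE
B_1_6,B_0_5,B_0_2,male,1967-07-01,B,FALSE
A_2_1,A_1_1,A_1_6,female,1975-07-01,A,TRUE
A_2_2,A_1_3,A_1_4,male,1976-07-01,A,TRUE
A_2_3,A_1_3,A_1_5,female,1975-07-01,A,TRUE
A_2_4,A_1_3,A_1_6,male,1976-07-01,A,TRUE
A_2_5,A_1_3,A_1_5,male,1975-07-01,A,TRUE
A_2_6,A_1_1,A_1_2,female,1976-07-01,A,TRUE
B_2_1,B_1_3,B_1_5,female,1977-07-01,B,TRUE
B_2_2,B_1_6,B_1_5,female,1975-07-01,B,TRUE
B_2_3,B_1_1,B_1_5,male,1977-07-01,B,TRUE
B_2_4,B_1_2,B_1_5,female,1975-07-01,B,TRUE
B_2_5,B_1_4,B_1_5,male,1976-07-01,B,TRUE
B_2_6,B_1_3,B_1_5,male,1976-07-01,B,TRUE
COMP_s1_1,A_2_2,B_2_2,male,1984-07-01,COMP,TRUE
COMP_s1_2,A_2_5,B_2_1,male,1986-07-01,COMP,TRUE
COMP_s1_3,A_2_5,B_2_1,male,1984-07-01,COMP,TRUE
COMP_s1_4,A_2_2,B_2_1,female,1985-07-01,COMP,TRUE
COMP_s2_1,A_2_2,COMP_s1_4,female,1993-07-01,COMP,TRUE
COMP_s2_2,A_2_2,COMP_s1_4,male,1994-07-01,COMP,TRUE
COMP_s2_3,A_2_2,COMP_s1_4,male,1993-07-01,COMP,TRUE
COMP_s2_4,A_2_2,COMP_s1_4,female,1994-07-01,COMP,TRUE
COMP_s3_1,B_2_3,COMP_s1_4,male,2000-07-01,COMP,TRUE
COMP_s3_2,B_2_5,COMP_s1_4,male,2001-07-01,COMP,TRUE
COMP_s3_3,B_2_6,COMP_s1_4,male,2001-07-01,COMP,TRUE
COMP_s3_4,B_2_5,COMP_s1_4,female,2001-07-01,COMP,TRUE
COMP_s5_2,COMP_s1_3,COMP_s1_4,male,2017-07-01,COMP,TRUE
COMP_s5_3,COMP_s1_2,COMP_s1_4,male,2018-07-01,COMP,TRUE
COMP_s4_1,COMP_s2_3,COMP_s3_4,female,2009-07-01,COMP,TRUE
COMP_s4_2,COMP_s2_3,COMP_s3_4,male,2010-07-01,COMP,TRUE
COMP_s4_3,COMP_s2_2,COMP_s3_4,female,2009-07-01,COMP,TRUE
COMP_s4_4,COMP_s2_2,COMP_s3_4,female,2010-07-01,COMP,TRUE
COMP_s5_1,COMP_s1_1,COMP_s4_1,female,2016-07-01,COMP,TRUE
COMP_s5_4,COMP_s1_3,COMP_s4_3,male,2017-07-01,COMP,TRUE
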