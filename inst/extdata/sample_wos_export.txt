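FN Export sample
VR 1.0
PT J
UT WOS:0001
AU Alpha, A; Second, B
TI A meta-analysis of something specific
SO J CLIN ONCOL
PY 2014
LA English
DT Article
DI 10.4000/meta.0001
CR SMITH J, 2001, J CLIN ONCOL, V19, P1001, DOI 10.1000/xyz
   JONES K, 1999, LANCET, V353, P1167
   ANONYMOUS, 1919, NY MED J
   LEE K, 1987, ANN INTERN MED, V107, P224
   GARCIA M, 2010, BMJ, V341, PC4444
ER
PT J
UT WOS:0002
AU Beta, B
TI A narrative review
SO COCHRANE DATABASE SYST REV
PY 2013
LA English
DT Review
DI 10.4000/rev.0002
CR SMITH J, 2001, J CLIN ONCOL, V19, P1001, DOI 10.1000/xyz; LEE K, 1987, ANN INTERN MED, V107, P224
ER
PT J
UT WOS:0003
AU Gamma, C
TI A case report with no references
SO J CASE REP
PY 2012
LA English
DT Article
DI 10.4000/case.0003
CR
ER
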