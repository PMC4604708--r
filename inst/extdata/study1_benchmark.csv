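meta_analysis,screened_original,included,screened_all,retrieved_all,screened_min2,retrieved_min2,screened_frequent,retrieved_frequent
Boothe,17500,8,5595,8,913,8,109,8
Frolkis,9151,12,967,10,224,7,108,6
Oliver-Williams,8646,10,588,8,62,5,62,5
Knoll,2365,21,7638,19,1719,18,132,11
Stevanovic,2090,13,987,12,186,10,77,10
De Vries,1194,9,8388,9,1924,9,124,8
Crider,1154,5,1006,5,120,5,120,5
Herretes,898,4,670,3,111,3,111,3
Gharaibeh,836,27,880,26,173,21,116,19
Gu,784,6,3234,6,780,6,129,5
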