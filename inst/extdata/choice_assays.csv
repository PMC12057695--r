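assay,deprivation_days,acclimation,choice
ST,7,ASW,social
ST,7,ASW,social
ST,7,ASW,social
ST,7,ASW,social
ST,7,ASW,social
ST,7,ASW,social
ST,7,ASW,social
ST,7,ASW,social
ST,7,ASW,social
ST,7,ASW,social
ST,7,ASW,social
ST,7,ASW,social
ST,7,ASW,social
ST,7,ASW,social
ST,7,ASW,social
ST,7,ASW,social
ST,7,ASW,social
ST,7,ASW,social
ST,7,ASW,social
ST,7,ASW,social
ST,7,ASW,social
ST,7,ASW,social
ST,7,ASW,social
ST,7,ASW,control
ST,7,ASW,control
ST,7,ASW,control
ST,7,ASW,control
ST,7,ASW,control
ST,7,ASW,control
ST,7,ASW,control
ST,7,ASW,control
ST,7,ASW,control
ST,7,ASW,control
ST,7,ASW,control
ST,7,ASW,control
ST,7,ASW,control
ST,7,ASW,control
ST,7,ASW,control
ST,7,ASW,control
ST,7,ASW,control
ST,7,ASW,none
ST,7,ASW,none
ST,7,ATW,social
ST,7,ATW,social
ST,7,ATW,social
ST,7,ATW,social
ST,7,ATW,social
ST,7,ATW,social
ST,7,ATW,control
ST,7,ATW,control
ST,7,ATW,control
ST,7,ATW,control
ST,7,ATW,control
ST,7,ATW,control
ST,7,ATW,control
ST,7,ATW,control
ST,7,ATW,control
ST,7,ATW,none
ST,3,ATW,social
ST,3,ATW,social
ST,3,ATW,social
ST,3,ATW,social
ST,3,ATW,social
ST,3,ATW,social
ST,3,ATW,social
ST,3,ATW,social
ST,3,ATW,social
ST,3,ATW,control
ST,3,ATW,control
ST,3,ATW,control
ST,3,ATW,control
ST,3,ATW,control
ST,3,ATW,control
ST,3,ATW,control
ST,3,ATW,control
ST,3,ATW,control
ST,3,ATW,none
FC,7,ASW,social
FC,7,ASW,social
FC,7,ASW,social
FC,7,ASW,social
FC,7,ASW,social
FC,7,ASW,social
FC,7,ASW,control
FC,7,ASW,control
FC,7,ASW,control
FC,7,ASW,control
FC,7,ASW,control
FC,7,ASW,control
FC,7,ASW,control
FC,7,ASW,control
FC,7,ASW,control
FC,7,ASW,control
FC,7,ASW,control
FC,7,ASW,control
FC,7,ASW,control
FC,7,ASW,control
FC,7,ASW,control
FC,7,ASW,control
FC,7,ASW,control
FC,7,ASW,control
FC,7,ASW,none
FC,7,ATW,social
FC,7,ATW,social
FC,7,ATW,social
FC,7,ATW,social
FC,7,ATW,social
FC,7,ATW,social
FC,7,ATW,social
FC,7,ATW,social
FC,7,ATW,social
FC,7,ATW,social
FC,7,ATW,social
FC,7,ATW,social
FC,7,ATW,social
FC,7,ATW,control
FC,7,ATW,control
FC,7,ATW,control
FC,7,ATW,control
FC,7,ATW,control
FC,7,ATW,control
FC,7,ATW,control
FC,7,ATW,control
FC,7,ATW,control
FC,7,ATW,control
FC,7,ATW,control
FC,7,ATW,control
FC,7,ATW,control
FC,7,ATW,control
FC,7,ATW,control
ST+FC,7,ASW,social
ST+FC,7,ASW,social
ST+FC,7,ASW,social
ST+FC,7,ASW,social
ST+FC,7,ASW,social
ST+FC,7,ASW,social
ST+FC,7,ASW,social
ST+FC,7,ASW,social
ST+FC,7,ASW,social
ST+FC,7,ASW,control
ST+FC,7,ASW,control
ST+FC,7,ASW,control
ST+FC,7,ASW,control
ST+FC,7,ASW,control
ST+FC,7,ASW,control
ST+FC,7,ASW,control
ST+FC,7,ASW,control
ST+FC,7,ASW,control
ST+FC,7,ASW,control
ST+FC,7,ASW,control
ST+FC,7,ASW,control
ST+FC,7,ASW,control
ST+FC,7,ASW,none
ST+FC,7,ASW,none
ST+FC,3,ATW,social
ST+FC,3,ATW,social
ST+FC,3,ATW,social
ST+FC,3,ATW,social
ST+FC,3,ATW,social
ST+FC,3,ATW,social
ST+FC,3,ATW,social
ST+FC,3,ATW,social
ST+FC,3,ATW,social
ST+FC,3,ATW,social
ST+FC,3,ATW,control
ST+FC,3,ATW,control
ST+FC,3,ATW,control
ST+FC,3,ATW,control
ST+FC,3,ATW,control
ST+FC,3,ATW,control
BA,7,ASW,social
BA,7,ASW,social
BA,7,ASW,social
BA,7,ASW,social
BA,7,ASW,social
BA,7,ASW,social
BA,7,ASW,social
BA,7,ASW,social
BA,7,ASW,social
BA,7,ASW,social
BA,7,ASW,social
BA,7,ASW,control
BA,7,ASW,control
BA,7,ASW,control
BA,7,ASW,control
BA,7,ASW,control
BA,7,ASW,control
BA,7,ASW,control
BA,7,ASW,control
BA,7,ASW,control
BA,7,ASW,control
BA,7,ASW,control
BA,7,ASW,control
BA,7,ASW,control
BA,7,ASW,control
BA,7,ASW,control
BA,7,ASW,control
BA,7,ASW,control
BA,7,ASW,none
BA,7,ASW,none
MA,7,ATW,social
MA,7,ATW,social
MA,7,ATW,social
MA,7,ATW,social
MA,7,ATW,social
MA,7,ATW,social
MA,7,ATW,social
MA,7,ATW,social
MA,7,ATW,control
MA,7,ATW,control
MA,7,ATW,control
MA,7,ATW,control
MA,7,ATW,control
MA,7,ATW,control
MA,7,ATW,control
MA,7,ATW,control
MA,7,ATW,control
MA,7,ATW,control
MA,7,ATW,control
MA,7,ATW,control
MA,7,ATW,control
MA,7,ATW,control
MA,7,ATW,control
MA,7,ATW,control
MA,7,ATW,control
MA,7,ATW,control
MA,7,ATW,control
MA,7,ATW,control
MA,7,ATW,control
MA,7,ATW,control
MA,7,ATW,none
MA,3,ATW,social
MA,3,ATW,social
MA,3,ATW,social
MA,3,ATW,social
MA,3,ATW,social
MA,3,ATW,social
MA,3,ATW,social
MA,3,ATW,control
MA,3,ATW,control
MA,3,ATW,control
MA,3,ATW,control
MA,3,ATW,control
MA,3,ATW,control
MA,3,ATW,control
MA,3,ATW,control
MA,3,ATW,control
MA,3,ATW,control
MA,3,ATW,none
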