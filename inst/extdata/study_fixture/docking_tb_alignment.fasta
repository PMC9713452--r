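>LTBP1_TB3
ASCTELVNGCSDTACLDVNGSCTALVNCGSCFPTACLVDNGESCTA
>FBN1_TB6
STCASVLDNCGDSTCVSLGENCASTLVCNGC--STCALSVDENCGS
>FBN2_TB6
TSCLTVAEGCNDTSCLTVNDGCSALVTCGNC--TSCLATVEEGCNS
>FBN3_TB6
GNCSALVDTCSEGNCAALVETCGSNLACTVC--GSCNLGADDTCSG
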