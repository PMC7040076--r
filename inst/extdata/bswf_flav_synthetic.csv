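# SYNTHETIC stand-in node table for a flavonoid-accumulation weighting
# function (FLAV). Not a transcription of any published action spectrum:
# it reproduces only the qualitative shape such spectra share (maximum
# effectiveness in the UV-B, roughly exponential decline through the
# UV-A, zero by 400 nm) and is normalised so weight = 1 at 300 nm.
lambda_nm,weight
280,2.95
285,2.30
290,1.80
295,1.36
300,1.00
305,0.71
310,0.50
315,0.35
320,0.245
330,0.120
340,0.059
350,0.029
360,0.0145
370,0.0071
380,0.0035
390,0.0017
400,0.0
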