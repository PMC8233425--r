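# Frozen oracle: Grantham (1974) distances evaluated independently from
# the published formula D = rho*[alpha*(c1-c2)^2 + beta*(p1-p2)^2 +
# gamma*(v1-v2)^2]^(1/2) with the published residue properties,
# rounded to the nearest integer. 190 unordered pairs.
grantham_oracle <- data.frame(
  aa1 = c(
  "S","S","S","S","S","S","S","S","S","S","S","S","S","S","S","S","S","S","S",
    "R","R","R","R","R","R","R","R","R","R","R","R","R","R","R","R","R","R",
    "L","L","L","L","L","L","L","L","L","L","L","L","L","L","L","L","L","P",
    "P","P","P","P","P","P","P","P","P","P","P","P","P","P","P","T","T","T",
    "T","T","T","T","T","T","T","T","T","T","T","T","A","A","A","A","A","A",
    "A","A","A","A","A","A","A","A","V","V","V","V","V","V","V","V","V","V",
    "V","V","V","G","G","G","G","G","G","G","G","G","G","G","G","I","I","I",
    "I","I","I","I","I","I","I","I","F","F","F","F","F","F","F","F","F","F",
    "Y","Y","Y","Y","Y","Y","Y","Y","Y","C","C","C","C","C","C","C","C","H",
    "H","H","H","H","H","H","Q","Q","Q","Q","Q","Q","N","N","N","N","N","K",
    "K","K","K","D","D","D","E","E","M"),
  aa2 = c(
  "R","L","P","T","A","V","G","I","F","Y","C","H","Q","N","K","D","E","M","W",
    "L","P","T","A","V","G","I","F","Y","C","H","Q","N","K","D","E","M","W",
    "P","T","A","V","G","I","F","Y","C","H","Q","N","K","D","E","M","W","T",
    "A","V","G","I","F","Y","C","H","Q","N","K","D","E","M","W","A","V","G",
    "I","F","Y","C","H","Q","N","K","D","E","M","W","V","G","I","F","Y","C",
    "H","Q","N","K","D","E","M","W","G","I","F","Y","C","H","Q","N","K","D",
    "E","M","W","I","F","Y","C","H","Q","N","K","D","E","M","W","F","Y","C",
    "H","Q","N","K","D","E","M","W","Y","C","H","Q","N","K","D","E","M","W",
    "C","H","Q","N","K","D","E","M","W","H","Q","N","K","D","E","M","W","Q",
    "N","K","D","E","M","W","N","K","D","E","M","W","K","D","E","M","W","D",
    "E","M","W","E","M","W","M","W","W"),
  d = c(
  109,144,73,58,99,123,55,142,155,143,112,89,68,46,121,65,80,135,177,102,103,
    71,111,96,125,98,97,77,180,29,43,85,26,96,54,92,101,98,92,96,32,138,5,22,
    36,197,99,112,152,106,172,138,14,61,38,27,68,42,95,114,110,169,76,75,90,
    103,108,94,87,147,58,69,59,89,103,92,149,47,41,65,78,85,66,81,128,64,60,
    94,113,112,195,85,91,110,106,126,107,84,148,109,30,50,55,191,84,96,133,97,
    152,121,22,88,135,153,147,158,98,87,79,126,94,98,127,184,21,33,197,94,109,
    149,102,168,134,10,61,22,204,100,116,158,102,177,140,29,40,194,83,99,142,
    85,160,123,35,37,174,154,139,202,154,169,196,214,24,68,32,81,41,86,115,46,
    53,61,29,101,130,94,23,41,141,174,101,57,94,109,45,160,191,126,152,67)
)
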