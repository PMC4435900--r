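# Amino-acid alphabet used throughout (20 canonical residues) and MEME's
# alphabetical ordering used for interchange output.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA_MEME <- sort(AA20)
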