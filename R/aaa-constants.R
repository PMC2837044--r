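## shared alphabets (collated first)

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## free positions in synthetic records exclude C and H so that planted
## zinc-finger anchors are the only ones in a record
FREE_AA <- setdiff(AA20, c("C", "H"))
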