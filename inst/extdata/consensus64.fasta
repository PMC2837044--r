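>tCWCH2_consensus64 synthetic worked example: 64-aa tandem-CWCH2 consensus
LVCKWDGCSEKLFDSPEELVDHVCEDHVGTQLEYTCLWKGCDRFPFKSRYKLIRHIRSHT
GEKP
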