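# synthetic PROSITE-style finger segments (NAME/start-end)
GLI1_LIKE/301-330
GLI1_LIKE/337-366
ZIC3_LIKE/1-28
ZIC3_LIKE/75-102
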