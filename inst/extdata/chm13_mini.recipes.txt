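# Composite mini-genome recipes (1-based inclusive source coordinates).
# One mini-chromosome per line; "+" concatenates segments, "xN" writes the
# segment N times in tandem.
GART-SON = chr21:31,912,598-31,959,322
Hist_Chr1 = chr1:148,935,900-149,012,900
Hist_Chr6 = chr6:25,878,304-26,154,469
rDNA = chr21:3,141,168-3,185,955 x16
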