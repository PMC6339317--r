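# sample() treats a length-1 numeric as 1:n; this never does
sample_one <- function(x) {
  x[sample.int(length(x), 1L)]
}
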