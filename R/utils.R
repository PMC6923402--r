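# Locale-independent (C collation) ordering for deterministic tie-breaks:
# radix sort compares raw bytes, so results do not depend on LC_COLLATE.
sort_c <- function(x) sort(x, method = "radix")

order_c <- function(..., decreasing = FALSE) {
  order(..., method = "radix", decreasing = decreasing)
}
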