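# Small shared helpers.

# Half-up decimal rounding (base round() rounds half to even).
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

# Single character at 0-based position of a string.
char_at0 <- function(sequence, pos0) {
  substr(sequence, pos0 + 1L, pos0 + 1L)
}
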