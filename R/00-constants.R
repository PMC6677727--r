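# Shared constants (sourced first).

BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

COUNT_COLS <- c(paste0(BASES, "_fwd"), paste0(BASES, "_rev"))

`%||%` <- function(a, b) if (is.null(a)) b else a
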