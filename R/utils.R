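# internal helpers shared across the package

`%||%` <- function(a, b) if (is.null(a)) b else a

hs_stop <- function(msg, class, call. = FALSE) {
  stop(structure(class = c(class, "hs_error", "error", "condition"),
                 list(message = msg, call = if (call.) sys.call(-1) else NULL)))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is_scalar_number(x))
    hs_stop(sprintf("`%s` must be a single finite number", name),
            "hs_config_error")
  if ((strict_lower && x <= lower) || (!strict_lower && x < lower) || x > upper)
    hs_stop(sprintf("`%s` = %g is outside its allowed range", name, x),
            "hs_config_error")
  invisible(x)
}

# full-precision numeric formatting so that written files round-trip exactly
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

hs_groups <- function() c("TGMHS", "NONTGMHS", "LAME", "CONTROL")
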