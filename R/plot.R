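#' @export
plot.temperature_series <- function(x, ...) {
  plot(age_days(x), x$temp_c, type = "l", xlab = "postnatal day",
       ylab = expression("CBT (" * degree * "C)"),
       main = paste("CBT,", x$animal_id[1]), ...)
  invisible(x)
}

#' @export
plot.band_power_series <- function(x, ...) {
  col <- ifelse(x$valid, "black", "grey70")
  plot(x$times_min / 1440, x$values, type = "l", col = "grey70",
       xlab = "postnatal day",
       ylab = if (x$normalized) "normalized band power" else "band power",
       main = sprintf("band [%g, %g] h", x$band[1], x$band[2]), ...)
  ok <- x$valid
  lines((x$times_min / 1440)[ok], x$values[ok], col = "black")
  invisible(x)
}
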