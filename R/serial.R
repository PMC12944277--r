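#' Encode a joint-angle triple as a fixed-width ASCII serial frame
#'
#' The PC-to-microcontroller link transmits hip, knee and ankle angles as a
#' 21-byte ASCII frame: three zero-padded `"%06.2f"` fields joined by commas
#' and terminated by a newline (`6 + 1 + 6 + 1 + 6 + 1 = 21` bytes). Angles
#' must lie in [0, 999.99]; precision on the wire is two decimals.
#'
#' @param hip,knee,ankle joint angles in degrees, each in [0, 999.99].
#' @return a single 21-character string.
#' @export
encode_angle_frame <- function(hip, knee, ankle) {
  a <- c(hip, knee, ankle)
  if (length(a) != 3 || anyNA(a) || any(!is.finite(a))) {
    abort("Need three finite angles.", class = "gaitloop_error_value")
  }
  if (any(a < 0 | a > 999.99)) {
    abort("Angles must lie in [0, 999.99] degrees.",
          class = "gaitloop_error_range")
  }
  paste0(paste(sprintf("%06.2f", a), collapse = ","), "\n")
}

#' Decode a 21-byte ASCII serial frame into joint angles
#'
#' Inverse of [encode_angle_frame()] at two-decimal precision. A payload of
#' the wrong length or with malformed fields raises a
#' `gaitloop_error_frame` condition; a streaming receiver treats that as a
#' dropped frame, never as a fatal error.
#'
#' @param payload a 21-character frame string.
#' @return named numeric vector `c(hip=, knee=, ankle=)`.
#' @export
decode_angle_frame <- function(payload) {
  if (!is.character(payload) || length(payload) != 1 ||
      nchar(payload, type = "bytes") != 21) {
    abort("Serial frame must be exactly 21 bytes.",
          class = "gaitloop_error_frame")
  }
  if (!grepl("^[0-9]{3}\\.[0-9]{2},[0-9]{3}\\.[0-9]{2},[0-9]{3}\\.[0-9]{2}\n$",
             payload)) {
    abort("Malformed serial frame.", class = "gaitloop_error_frame")
  }
  vals <- as.numeric(strsplit(sub("\n$", "", payload), ",",
                              fixed = TRUE)[[1]])
  setNames(vals, c("hip", "knee", "ankle"))
}

#' Analytic serial transmission time
#'
#' Time to clock `n_bytes` over a UART at `baud` bits per second, with
#' `bits_per_byte` bits on the wire per payload byte (default 10: one start
#' bit, eight data bits, one stop bit). For the 21-byte angle frame this
#' gives 1.823 ms at 115,200 bps and ~0.23 ms at 921,600 bps.
#'
#' @param n_bytes payload size in bytes.
#' @param baud line rate in bits per second.
#' @param bits_per_byte wire bits per payload byte (default 10, 8N1 framing).
#' @return transmission time in milliseconds.
#' @export
serial_transmission_time <- function(n_bytes, baud, bits_per_byte = 10) {
  if (n_bytes <= 0 || baud <= 0 || bits_per_byte <= 0) {
    abort("All serial-model inputs must be positive.",
          class = "gaitloop_error_value")
  }
  n_bytes * bits_per_byte / baud * 1000
}
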