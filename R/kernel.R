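#' Single-polymerase MS2 fluorescence kernel
#'
#' Signal contributed by one Pol II as a function of time since its
#' initiation, in molecule-equivalents. The signal is 0 until the polymerase
#' reaches the loop cassette, ramps linearly to exactly 1 while the cassette
#' is transcribed (loops appear co-transcriptionally), stays at 1 while the
#' remaining gene body is transcribed and during terminal retention of the
#' transcript at the locus, then drops to 0 on release.
#'
#' @param loop_start_bp Distance from the transcription start site to the
#'   first MS2 loop (bases).
#' @param post_loop_bp Bases remaining after the cassette, including any
#'   reporter extension (e.g. a LacZ tail used to lengthen the RNA).
#' @param elongation_bp_s Pol II elongation rate (bases / s).
#' @param retention_s Retention of the finished transcript at the locus (s).
#' @param frame_interval_s Sampling interval the kernel will be used at (s).
#' @param cassette_bp Length of the MS2 loop cassette (default 1300 bp,
#'   a 24x loop array).
#' @return An object of class `ms2_kernel`.
#' @export
build_kernel <- function(loop_start_bp, post_loop_bp, elongation_bp_s,
                         retention_s, frame_interval_s,
                         cassette_bp = 1300) {
  if (elongation_bp_s <= 0) stop("elongation rate must be > 0")
  if (any(c(loop_start_bp, post_loop_bp, retention_s, cassette_bp) < 0))
    stop("lengths and times must be >= 0")
  if (frame_interval_s <= 0) stop("frame_interval_s must be > 0")
  t_rise <- loop_start_bp / elongation_bp_s
  t_full <- (loop_start_bp + cassette_bp) / elongation_bp_s
  t_end <- (loop_start_bp + cassette_bp + post_loop_bp) / elongation_bp_s +
    retention_s
  structure(list(loop_start_bp = loop_start_bp, cassette_bp = cassette_bp,
                 post_loop_bp = post_loop_bp,
                 elongation_bp_s = elongation_bp_s,
                 retention_s = retention_s,
                 frame_interval_s = frame_interval_s,
                 t_rise = t_rise, t_full = t_full, t_end = t_end),
            class = "ms2_kernel")
}

#' Kernel presets for the two reporter geometries
#'
#' `"loops-near-TSS"` places the loop cassette just downstream of the
#' transcription start so the signal rises early; `"loops-near-3p"` places it
#' near the 3' end so the signal rises late. Total transcription unit length
#' is equal between the presets. Elongation rate and retention time are
#' modelling assumptions (defaults 45 bp/s and 30 s), not measured values.
#'
#' @param preset `"loops-near-TSS"` or `"loops-near-3p"`.
#' @param frame_interval_s Sampling interval in seconds.
#' @param elongation_bp_s,retention_s Override the default assumptions.
#' @return An `ms2_kernel`.
#' @export
kernel_preset <- function(preset = c("loops-near-TSS", "loops-near-3p"),
                          frame_interval_s = 20,
                          elongation_bp_s = 45, retention_s = 30) {
  preset <- match.arg(preset)
  if (preset == "loops-near-TSS")
    build_kernel(loop_start_bp = 150, post_loop_bp = 4000,
                 elongation_bp_s = elongation_bp_s, retention_s = retention_s,
                 frame_interval_s = frame_interval_s)
  else
    build_kernel(loop_start_bp = 3000, post_loop_bp = 1150,
                 elongation_bp_s = elongation_bp_s, retention_s = retention_s,
                 frame_interval_s = frame_interval_s)
}

#' Evaluate a kernel at times since initiation
#'
#' @param kernel An `ms2_kernel`.
#' @param tau Numeric vector of times since initiation (s).
#' @return Signal in molecule-equivalents, in \[0, 1\].
#' @export
kernel_eval <- function(kernel, tau) {
  out <- numeric(length(tau))
  ramp <- tau > kernel$t_rise & tau < kernel$t_full
  out[ramp] <- (tau[ramp] - kernel$t_rise) / (kernel$t_full - kernel$t_rise)
  out[tau >= kernel$t_full & tau < kernel$t_end] <- 1
  out
}

#' Total support length of the kernel, in seconds
#' @param kernel An `ms2_kernel`.
#' @export
kernel_support_s <- function(kernel) kernel$t_end

#' @export
print.ms2_kernel <- function(x, ...) {
  cat(sprintf(paste0("<ms2_kernel> rise %.1f-%.1f s, release at %.1f s ",
                     "(%g bp/s, retention %g s)\n"),
              x$t_rise, x$t_full, x$t_end, x$elongation_bp_s, x$retention_s))
  invisible(x)
}
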