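# Gradient-coil specifications, bundled presets, and the minimum-duration
# trapezoid primitive that underlies every readout and diffusion lobe.

#' Construct a gradient-coil specification
#'
#' A coil is described by an absolute amplitude limit (`g_abs_max`, reachable
#' at low duty cycle, e.g. diffusion lobes), a duty-cycle-limited nominal
#' amplitude (`g_nom_max`, sustainable through an EPI readout train), a slew
#' rate limit, and optional forbidden echo-spacing bands where mechanical
#' resonances prohibit operation.
#'
#' @param name coil name.
#' @param g_abs_max_mT_per_m absolute amplitude limit, mT/m.
#' @param g_nom_max_mT_per_m duty-cycle-limited nominal amplitude, mT/m.
#' @param sr_max_T_per_m_per_s slew-rate limit, T/m/s.
#' @param forbidden_es_bands_ms list of length-2 numeric vectors, closed
#'   echo-spacing intervals in ms that must be avoided.
#' @param sensitivity_mT_per_m_per_A optional coil sensitivity.
#' @param linearity_pct optional per-axis linearity on a 20 cm sphere.
#' @return an object of class `gradient_coil`.
#' @export
gradient_coil <- function(name, g_abs_max_mT_per_m, g_nom_max_mT_per_m,
                          sr_max_T_per_m_per_s,
                          forbidden_es_bands_ms = list(),
                          sensitivity_mT_per_m_per_A = NA_real_,
                          linearity_pct = NA_real_) {
  g_abs <- as.numeric(g_abs_max_mT_per_m)
  g_nom <- as.numeric(g_nom_max_mT_per_m)
  sr <- as.numeric(sr_max_T_per_m_per_s)
  if (!is.finite(g_abs) || g_abs <= 0) stop("g_abs_max must be positive")
  if (!is.finite(g_nom) || g_nom <= 0 || g_nom > g_abs)
    stop("g_nom_max must satisfy 0 < g_nom_max <= g_abs_max")
  if (!is.finite(sr) || sr <= 0) stop("sr_max must be positive")
  bands <- lapply(forbidden_es_bands_ms, function(b) {
    b <- as.numeric(b)
    if (length(b) != 2L || any(!is.finite(b)) || b[1] > b[2])
      stop("each forbidden band must be a finite interval [lo, hi] with lo <= hi")
    b
  })
  if (length(bands) > 1L) {
    o <- order(vapply(bands, `[`, numeric(1), 1L))
    bands <- bands[o]
    lo <- vapply(bands, `[`, numeric(1), 1L)
    hi <- vapply(bands, `[`, numeric(1), 2L)
    if (any(lo[-1] <= hi[-length(hi)])) stop("forbidden bands must be disjoint")
  }
  structure(
    list(name = as.character(name),
         g_abs_max = g_abs, g_nom_max = g_nom, sr_max = sr,
         forbidden_es_bands = bands,
         sensitivity = as.numeric(sensitivity_mT_per_m_per_A),
         linearity_pct = as.numeric(linearity_pct)),
    class = "gradient_coil")
}

#' @export
print.gradient_coil <- function(x, ...) {
  cat(sprintf("Gradient coil '%s'\n", x$name))
  cat(sprintf("  Gmax (absolute):      %g mT/m\n", x$g_abs_max))
  cat(sprintf("  Gmax (nominal, EPI):  %g mT/m\n", x$g_nom_max))
  cat(sprintf("  Slew rate:            %g T/m/s\n", x$sr_max))
  if (length(x$forbidden_es_bands))
    cat("  Forbidden ES bands (ms):",
        paste(vapply(x$forbidden_es_bands,
                     function(b) sprintf("[%g, %g]", b[1], b[2]), ""),
              collapse = ", "), "\n")
  invisible(x)
}

# Preset table.  Impulse slew rate is 900 T/m/s (its specified EPI operating
# point); AC84 is the 7T head-insert, xr_body the whole-body coil with its
# duty-cycle-limited 40 mT/m nominal amplitude.
.coil_presets <- function() {
  list(
    impulse = gradient_coil(
      "impulse", 200, 85, 900,
      forbidden_es_bands_ms = list(c(0.26, 0.26), c(0.35, 0.36),
                                   c(0.46, 0.48), c(0.82, 0.92))),
    ac84 = gradient_coil("ac84", 80, 50, 333),
    xr_body = gradient_coil("xr_body", 80, 40, 200)
  )
}

#' Load a bundled coil preset or a coil spec file
#'
#' Presets: `"impulse"` (200/85 mT/m, 900 T/m/s, with forbidden echo-spacing
#' bands), `"ac84"` (80/50 mT/m, 333 T/m/s), `"xr_body"` (80/40 mT/m,
#' 200 T/m/s).  Any other string is treated as a path to a flat key/value
#' spec file (see [read_coil_spec()]).
#'
#' @param name preset name or file path.
#' @return a [gradient_coil()] object.
#' @examples
#' load_coil_preset("impulse")
#' @export
load_coil_preset <- function(name) {
  presets <- .coil_presets()
  if (name %in% names(presets)) return(presets[[name]])
  if (file.exists(name)) return(read_coil_spec(name))
  stop(sprintf("unknown coil preset '%s' (available: %s) and no such file",
               name, paste(names(presets), collapse = ", ")))
}

#' Read / write a coil spec as a flat key/value file
#'
#' Format: one `key: value` pair per line; keys `name`,
#' `g_abs_max_mT_per_m`, `g_nom_max_mT_per_m`, `sr_max_T_per_m_per_s` are
#' required; `forbidden_es_bands_ms` is an optional semicolon-separated list
#' of `lo,hi` pairs.  Lines starting with `#` are comments.
#'
#' @param path file path.
#' @return `read_coil_spec`: a [gradient_coil()]; `write_coil_spec`: `path`,
#'   invisibly.
#' @export
read_coil_spec <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(p) paste(p[-1], collapse = ":"), ""))
  names(vals) <- keys
  need <- c("name", "g_abs_max_mT_per_m", "g_nom_max_mT_per_m",
            "sr_max_T_per_m_per_s")
  missing <- setdiff(need, keys)
  if (length(missing))
    stop(sprintf("coil spec file '%s' is missing field(s): %s",
                 path, paste(missing, collapse = ", ")))
  bands <- list()
  if ("forbidden_es_bands_ms" %in% keys && nzchar(vals[["forbidden_es_bands_ms"]])) {
    bands <- lapply(strsplit(vals[["forbidden_es_bands_ms"]], ";")[[1]],
                    function(s) as.numeric(strsplit(trimws(s), ",")[[1]]))
  }
  gradient_coil(vals[["name"]],
                as.numeric(vals[["g_abs_max_mT_per_m"]]),
                as.numeric(vals[["g_nom_max_mT_per_m"]]),
                as.numeric(vals[["sr_max_T_per_m_per_s"]]),
                forbidden_es_bands_ms = bands)
}

#' @rdname read_coil_spec
#' @param coil a [gradient_coil()] object.
#' @export
write_coil_spec <- function(coil, path) {
  stopifnot(inherits(coil, "gradient_coil"))
  bands <- paste(vapply(coil$forbidden_es_bands,
                        function(b) sprintf("%g,%g", b[1], b[2]), ""),
                 collapse = "; ")
  writeLines(c(
    sprintf("name: %s", coil$name),
    sprintf("g_abs_max_mT_per_m: %g", coil$g_abs_max),
    sprintf("g_nom_max_mT_per_m: %g", coil$g_nom_max),
    sprintf("sr_max_T_per_m_per_s: %g", coil$sr_max),
    sprintf("forbidden_es_bands_ms: %s", bands)), path)
  invisible(path)
}

#' Shortest symmetric trapezoid achieving a gradient area
#'
#' Solves for the minimum-duration symmetric trapezoid (degenerating to a
#' triangle when the amplitude limit is not reached) with the requested
#' zeroth moment, under the coil's amplitude and slew limits.  Timing is
#' continuous (no raster rounding).  The conventional area identity for a
#' symmetric trapezoid with ramp time r and flat time f is
#' `area = amplitude * (f + r)`.
#'
#' @param target_area requested area, (mT/m)*ms; must be positive.
#' @param coil a [gradient_coil()].
#' @param use_abs_limit if `TRUE` the absolute amplitude limit applies
#'   (diffusion lobes); otherwise the duty-cycle nominal limit (EPI readout).
#' @return an object of class `trapezoid_pulse` with fields `amplitude`
#'   (mT/m), `ramp_ms`, `flat_ms`, `area`, `duration_ms`.
#' @examples
#' trapezoid_for_area(39.146, load_coil_preset("xr_body"))
#' @export
trapezoid_for_area <- function(target_area, coil, use_abs_limit = FALSE) {
  stopifnot(inherits(coil, "gradient_coil"))
  if (!is.finite(target_area) || target_area <= 0)
    stop("target_area must be positive")
  gmax <- if (use_abs_limit) coil$g_abs_max else coil$g_nom_max
  sr <- coil$sr_max # mT/m/ms numerically
  tri_capacity <- gmax^2 / sr # area of the steepest triangle peaking at gmax
  if (target_area <= tri_capacity) {
    amp <- sqrt(target_area * sr)
    ramp <- amp / sr
    flat <- 0
  } else {
    amp <- gmax
    ramp <- gmax / sr
    flat <- target_area / gmax - ramp
  }
  structure(list(amplitude = amp, ramp_ms = ramp, flat_ms = flat,
                 area = amp * (flat + ramp),
                 duration_ms = 2 * ramp + flat),
            class = "trapezoid_pulse")
}

#' @export
print.trapezoid_pulse <- function(x, ...) {
  cat(sprintf(
    "Trapezoid: amplitude %.3f mT/m, ramp %.4f ms, flat %.4f ms, area %.3f (mT/m)*ms, duration %.4f ms\n",
    x$amplitude, x$ramp_ms, x$flat_ms, x$area, x$duration_ms))
  invisible(x)
}
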