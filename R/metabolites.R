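#' Eicosanoid reference anchors
#'
#' Retention-time / \[M-H\]- m/z anchors for the eicosanoids relevant to
#' coral dioxygenase products: arachidonic acid (AA), the HETE positional
#' isomers (all m/z 319.2, separated chromatographically), the stable allene
#' oxide end products alpha-ketol (335.2) and cyclopentenone (317.2), and the
#' prostaglandins PGF2a (353.2), PGE2 and PGD2 (both 351.2; PGD2 has no
#' retention-time anchor, so m/z-only hits at 351.2 stay ambiguous).
#' Aldehyde products have no printed anchors and are excluded.
#'
#' @return Data frame with columns `name`, `rt` (minutes, `NA` when unknown)
#'   and `mz` (negative-mode \[M-H\]-, `NA` for radio/UV-only species).
#' @export
eicosanoid_refs <- function() {
  data.frame(
    name = c("AA", "8-HETE", "15-HETE", "11-HETE", "5-HETE",
             "alpha-ketol", "cyclopentenone", "PGF2a", "PGE2", "PGD2"),
    rt = c(19.9, 17.2, 16.8, 17.0, 17.4, NA, NA, 6.9, 8.5, NA),
    mz = c(NA, 319.2, 319.2, 319.2, 319.2, 335.2, 317.2, 353.2, 351.2, 351.2),
    stringsAsFactors = FALSE)
}

#' Read a peak table from CSV
#'
#' Expected columns: `rt` (minutes), `mz` (empty for radio/UV peaks), `area`,
#' `channel` (`radio`, `uv235` or `ms`); an optional `condition` column (e.g.
#' an EDTA tag) is carried through untouched.
#'
#' @param path CSV file path.
#' @return Validated peak data frame.
#' @export
read_peaks <- function(path) {
  peaks <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(peaks)[names(peaks) == "rt_min"] <- "rt"
  validate_peaks(peaks)
}

validate_peaks <- function(peaks) {
  need <- c("rt", "area", "channel")
  missing <- setdiff(need, names(peaks))
  if (length(missing))
    cx_stop("coralox_format_error",
            sprintf("peak table lacks column(s): %s",
                    paste(missing, collapse = ", ")))
  if (!"mz" %in% names(peaks)) peaks$mz <- NA_real_
  if (!"condition" %in% names(peaks)) peaks$condition <- "standard"
  if (!all(peaks$channel %in% c("radio", "uv235", "ms")))
    cx_stop("coralox_format_error",
            "channel must be one of radio, uv235, ms")
  if (any(peaks$area < 0) || any(peaks$rt < 0))
    cx_stop("coralox_format_error", "negative area or retention time")
  bad_mz <- (peaks$channel == "ms" & is.na(peaks$mz)) |
    (peaks$channel != "ms" & !is.na(peaks$mz))
  if (any(bad_mz))
    cx_stop("coralox_format_error",
            "m/z must be present exactly for ms-channel peaks")
  peaks
}

#' Assign peaks to eicosanoid references
#'
#' Each peak is compared against every reference on the fields both sides
#' carry (retention time, m/z). References passing all applicable tolerance
#' gates are candidates; the assignment minimises the tolerance-normalised
#' distance, preferring candidates matched on more fields. A peak is flagged
#' `ambiguous` when the best candidate ties with another, or when the match
#' rests on m/z alone while other references share that m/z within
#' tolerance (the PGE2/PGD2 situation at 351.2).
#'
#' @param peaks Peak data frame (see [read_peaks()]).
#' @param refs Reference table (see [eicosanoid_refs()]).
#' @param rt_tol Retention-time tolerance in minutes (default 0.2, which
#'   preserves the 16.8/17.0/17.2/17.4 HETE isomer separations).
#' @param mz_tol m/z tolerance (default 0.05; anchors are printed to one
#'   decimal).
#' @return `peaks` with added columns `metabolite` (`"unassigned"` when no
#'   reference passes), `delta_rt`, `delta_mz`, `ambiguous`, `alternatives`
#'   (comma-separated).
#' @export
assign_peaks <- function(peaks, refs = eicosanoid_refs(),
                         rt_tol = 0.2, mz_tol = 0.05) {
  peaks <- validate_peaks(peaks)
  if (is.null(refs) || !nrow(refs))
    cx_stop("coralox_config_error", "empty metabolite reference table")
  stopifnot(rt_tol > 0, mz_tol > 0)
  n <- nrow(peaks)
  peaks$metabolite <- "unassigned"
  peaks$delta_rt <- NA_real_
  peaks$delta_mz <- NA_real_
  peaks$ambiguous <- FALSE
  peaks$alternatives <- ""
  for (i in seq_len(n)) {
    cand <- match_candidates(peaks$rt[i], peaks$mz[i], refs, rt_tol, mz_tol)
    if (!nrow(cand)) next
    best <- cand[1L, ]
    peaks$metabolite[i] <- best$name
    peaks$delta_rt[i] <- best$delta_rt
    peaks$delta_mz[i] <- best$delta_mz
    others <- cand$name[-1L]
    tie <- nrow(cand) > 1L && cand$n_fields[2L] == best$n_fields &&
      abs(cand$dist[2L] - best$dist) < 1e-9
    mz_only <- is.na(best$delta_rt) && !is.na(best$delta_mz)
    shared_mz <- character()
    if (mz_only) {
      shared_mz <- setdiff(
        refs$name[!is.na(refs$mz) & abs(refs$mz - peaks$mz[i]) <= mz_tol],
        best$name)
    }
    peaks$ambiguous[i] <- tie || (mz_only && length(shared_mz) > 0L)
    peaks$alternatives[i] <- paste(unique(c(others, shared_mz)), collapse = ",")
  }
  peaks
}

# candidates passing all applicable gates, ordered by fields-compared (desc)
# then normalised distance (asc); deterministic tie-break on table order
match_candidates <- function(rt, mz, refs, rt_tol, mz_tol) {
  d_rt <- ifelse(!is.na(rt) & !is.na(refs$rt), rt - refs$rt, NA_real_)
  d_mz <- ifelse(!is.na(mz) & !is.na(refs$mz), mz - refs$mz, NA_real_)
  n_fields <- (!is.na(d_rt)) + (!is.na(d_mz))
  pass <- n_fields > 0L &
    (is.na(d_rt) | abs(d_rt) <= rt_tol) &
    (is.na(d_mz) | abs(d_mz) <= mz_tol)
  cand <- data.frame(name = refs$name, delta_rt = d_rt, delta_mz = d_mz,
                     n_fields = n_fields, stringsAsFactors = FALSE)[pass, , drop = FALSE]
  if (!nrow(cand)) return(cand)
  norm2 <- function(drt, dmz) {
    v <- c(if (!is.na(drt)) (drt / rt_tol)^2, if (!is.na(dmz)) (dmz / mz_tol)^2)
    sqrt(mean(v))
  }
  cand$dist <- mapply(norm2, cand$delta_rt, cand$delta_mz)
  cand[order(-cand$n_fields, cand$dist), , drop = FALSE]
}

#' Substrate conversion rate from a radiochromatogram
#'
#' The conversion rate is the percentage of total radiolabelled peak area
#' found outside the substrate's retention-time window, i.e. the
#' product-area fraction: `100 * sum(product areas) / sum(all areas)`.
#'
#' @param peaks Peak data frame; only `channel == "radio"` rows are used.
#' @param substrate Metabolite name of the substrate (default `"AA"`,
#'   arachidonic acid, rt anchor 19.9 min).
#' @param refs Reference table carrying the substrate's retention time.
#' @param rt_tol Retention-time window half-width (minutes).
#' @return Conversion rate in percent.
#' @export
conversion_rate <- function(peaks, substrate = "AA", refs = eicosanoid_refs(),
                            rt_tol = 0.2) {
  peaks <- validate_peaks(peaks)
  radio <- peaks[peaks$channel == "radio", , drop = FALSE]
  if (!nrow(radio))
    cx_stop("coralox_contract_error", "no radio-channel peaks")
  ref_rt <- refs$rt[refs$name == substrate]
  if (!length(ref_rt) || is.na(ref_rt))
    cx_stop("coralox_config_error",
            sprintf("substrate '%s' has no retention-time anchor", substrate))
  total <- sum(radio$area)
  if (total <= 0)
    cx_stop("coralox_undefined_rate_error", "total radio peak area is zero")
  is_substrate <- abs(radio$rt - ref_rt) <= rt_tol
  100 * sum(radio$area[!is_substrate]) / total
}
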