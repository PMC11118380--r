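#' Truncated unit-peak Gaussian smoothing kernel
#'
#' Kernel used to smooth residue indicator tracks.  The standard deviation
#' derives from the full width at half maximum, `sigma = fwhm /
#' (2 sqrt(2 ln 2))` (FWHM 5 gives sigma = 2.12).  Weights are
#' `exp(-k^2 / (2 sigma^2))` for offsets `|k| <= floor(span/2)` — a
#' unit-peak (amplitude 1 at offset 0) kernel, so a smoothed histidine
#' track reads in histidine equivalents and an isolated residue peaks at
#' exactly 1.  "Spanning 20 residues" is implemented as offsets -10..+10
#' (21 symmetric taps; the outermost taps weigh < 2e-5).
#'
#' @param fwhm full width at half maximum, residues.
#' @param span kernel footprint in residues; support is
#'   `-floor(span/2) .. +floor(span/2)`.
#' @return list of class `SmoothingKernel`: `fwhm`, `sigma`, `span`,
#'   `half`, `offsets`, `weights`.
#' @export
make_kernel <- function(fwhm = 5, span = 20) {
  if (!is.numeric(fwhm) || fwhm <= 0) stop("fwhm must be positive")
  if (!is.numeric(span) || span < 1) stop("span must be >= 1")
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  half <- floor(span / 2)
  offsets <- seq.int(-half, half)
  weights <- exp(-offsets^2 / (2 * sigma^2))
  structure(list(fwhm = fwhm, sigma = sigma, span = span, half = half,
                 offsets = offsets, weights = weights),
            class = "SmoothingKernel")
}

#' Binary indicator of a residue set along a sequence
#'
#' @param sequence amino-acid string (uppercase; lowercase is accepted and
#'   uppercased).
#' @param residues character vector of single-letter codes.
#' @return integer vector, 1 where the residue belongs to `residues`.
#' @export
residue_indicator <- function(sequence, residues) {
  if (!length(residues)) stop("residues must be non-empty")
  chars <- strsplit(toupper(sequence), "")[[1]]
  as.integer(chars %in% toupper(residues))
}

#' Smooth a per-residue track with a truncated kernel
#'
#' Discrete convolution with zero padding: positions beyond either
#' terminus contribute nothing (absent residues carry no charge).  Output
#' length equals input length.
#'
#' @param x numeric vector (e.g. a residue indicator).
#' @param kernel a [make_kernel()] object.
#' @return numeric vector, same length as `x`.
#' @export
smooth_profile <- function(x, kernel = make_kernel()) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  # direct shift-accumulate convolution (exact, no FFT roundoff)
  out <- numeric(n)
  idx <- seq_len(n)
  for (k in seq_along(kernel$offsets)) {
    src <- idx + kernel$offsets[k]
    ok <- src >= 1L & src <= n
    out[ok] <- out[ok] + kernel$weights[k] * x[src[ok]]
  }
  out
}

#' Delta-charge profile of a protein
#'
#' Expected protonation-charge gain of the local sequence window when pH
#' drops from 7.4 to 6.5, dominated by histidine (side-chain pKa near 6):
#' the Gaussian-smoothed histidine indicator, in histidine equivalents.
#' `his_weight = 1` treats each histidine as one chargeable unit; set it
#' to [his_protonation_delta()]`(7.4, 6.5)` for a fractional-protonation
#' profile instead.
#'
#' @param sequence amino-acid string.
#' @param kernel a [make_kernel()] object.
#' @param his_weight charge units contributed per histidine.
#' @return numeric vector, one Delta-charge value per residue.
#' @export
delta_charge_profile <- function(sequence, kernel = make_kernel(),
                                 his_weight = 1) {
  smooth_profile(residue_indicator(sequence, "H") * his_weight, kernel)
}

#' Call peaks in a smoothed profile
#'
#' Local maxima with value strictly above `charge_threshold`; plateaus
#' count once at their first position.  Maxima closer than
#' `min_peak_separation` are merged keeping the larger value (ties broken
#' toward the smaller index).  Output is sorted by position.
#'
#' @param profile numeric vector, e.g. from [delta_charge_profile()].
#' @param charge_threshold strict lower bound for a peak value.
#' @param min_peak_separation minimum distance (residues) between
#'   reported peaks.
#' @return integer vector of 1-based peak positions.
#' @export
find_peaks <- function(profile, charge_threshold = 1,
                       min_peak_separation = 20) {
  if (charge_threshold <= 0) stop("charge_threshold must be positive")
  n <- length(profile)
  if (n == 0L) return(integer(0))
  # compress to runs so a plateau counts once (at its first position) and
  # a shoulder on a monotone slope is not a maximum
  r <- rle(profile)
  v <- r$values
  starts <- cumsum(r$lengths) - r$lengths + 1L
  prev <- c(-Inf, v[-length(v)])
  nxt <- c(v[-1], -Inf)
  cand <- starts[v > charge_threshold & v > prev & v > nxt]
  if (!length(cand)) return(integer(0))
  # greedy merge: take peaks by decreasing value (ties: smaller index)
  ord <- order(-profile[cand], cand)
  accepted <- integer(0)
  for (i in cand[ord]) {
    if (!length(accepted) || all(abs(accepted - i) >= min_peak_separation))
      accepted <- c(accepted, i)
  }
  sort(accepted)
}

#' Extend a peak into a candidate region
#'
#' Adds `flank` residues on each side of the peak, clipped to the
#' sequence, giving an interval of at most `2 * flank + 1` residues
#' (1-based inclusive).
#'
#' @param peak_pos peak position.
#' @param flank residues added on each side (default 50).
#' @param seq_length protein length.
#' @return integer vector `c(start, end)`.
#' @export
extend_region <- function(peak_pos, flank = 50, seq_length) {
  if (peak_pos < 1 || peak_pos > seq_length) stop("peak_pos out of bounds")
  c(max(1L, as.integer(peak_pos) - as.integer(flank)),
    min(as.integer(seq_length), as.integer(peak_pos) + as.integer(flank)))
}

#' Per-side disorder assessment of a candidate region
#'
#' Averages per-residue disorder scores separately over the N-terminal
#' side (`start .. peak-1`) and the C-terminal side (`peak+1 .. end`) of
#' the peak (an empty side scores 0).  The region counts as disordered if
#' either side exceeds `threshold`.
#'
#' @param scores numeric vector of per-residue scores in `[0, 1]` for the
#'   whole protein (from a sidecar table or a pluggable predictor).
#' @param region integer `c(start, end)` from [extend_region()].
#' @param peak_pos peak position inside `region`.
#' @param threshold consensus-score cutoff (default 0.3, strict).
#' @param aggregate `"mean"` (default) or `"max"` per side.
#' @return list with `disorder_n`, `disorder_c`, `disordered`.
#' @export
assess_disorder <- function(scores, region, peak_pos, threshold = 0.3,
                            aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "mean") mean else max
  side <- function(idx) if (length(idx)) agg(scores[idx]) else 0
  n_idx <- if (peak_pos - 1 >= region[1]) region[1]:(peak_pos - 1) else integer(0)
  c_idx <- if (peak_pos + 1 <= region[2]) (peak_pos + 1):region[2] else integer(0)
  dn <- side(n_idx); dc <- side(c_idx)
  list(disorder_n = dn, disorder_c = dc,
       disordered = dn > threshold | dc > threshold)
}

#' Proline/glutamine enrichment score of a candidate region
#'
#' Smooths the proline and glutamine indicators separately with the same
#' kernel as the charge profile and sums the two tracks; the score is the
#' larger of the two side maxima (N side `start .. peak-1`, C side
#' `peak+1 .. end`) within the region.
#'
#' @param sequence amino-acid string.
#' @param peak_pos Delta-charge peak position.
#' @param region integer `c(start, end)`.
#' @param kernel a [make_kernel()] object.
#' @return numeric PQ score (0 when the region contains no P or Q).
#' @export
pq_score <- function(sequence, peak_pos, region, kernel = make_kernel()) {
  prof <- smooth_profile(residue_indicator(sequence, "P"), kernel) +
          smooth_profile(residue_indicator(sequence, "Q"), kernel)
  side_max <- function(idx) if (length(idx)) max(prof[idx]) else 0
  n_idx <- if (peak_pos - 1 >= region[1]) region[1]:(peak_pos - 1) else integer(0)
  c_idx <- if (peak_pos + 1 <= region[2]) (peak_pos + 1):region[2] else integer(0)
  max(side_max(n_idx), side_max(c_idx))
}

#' Histidine protonation fraction (Henderson-Hasselbalch)
#'
#' Fraction of histidine side chains protonated at a given pH:
#' `f = 1 / (1 + 10^(pH - pKa))`.
#'
#' @param pH solution pH.
#' @param pKa histidine side-chain pKa (default 6.0).
#' @return protonation fraction in `[0, 1]`.
#' @export
his_protonation_fraction <- function(pH, pKa = 6.0) {
  1 / (1 + 10^(pH - pKa))
}

#' Protonation gain between two pH values
#'
#' @param pH_a starting pH (e.g. 7.4).
#' @param pH_b ending pH (e.g. 6.5).
#' @param pKa histidine side-chain pKa.
#' @return `f(pH_b) - f(pH_a)`, the per-histidine charge gain on
#'   acidification (about 0.20 for 7.4 to 6.5 at pKa 6).
#' @export
his_protonation_delta <- function(pH_a, pH_b, pKa = 6.0) {
  his_protonation_fraction(pH_b, pKa) - his_protonation_fraction(pH_a, pKa)
}

#' Net charge of a sequence interval
#'
#' Integer side-chain model: +1 per lysine/arginine, -1 per
#' aspartate/glutamate.  Histidine contributes 0 in `"pH74"` mode and its
#' Henderson-Hasselbalch protonation fraction in `"acidic"` mode.  An
#' approximation: terminal charges and context-shifted pKa values are
#' ignored.
#'
#' @param sequence amino-acid string.
#' @param interval optional `c(start, end)`; default whole sequence.
#' @param mode `"pH74"` or `"acidic"`.
#' @param pH pH used in acidic mode.
#' @param pKa histidine pKa.
#' @return net charge (real).
#' @export
net_charge <- function(sequence, interval = NULL,
                       mode = c("pH74", "acidic"), pH = 6.5, pKa = 6.0) {
  mode <- match.arg(mode)
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (!is.null(interval)) chars <- chars[interval[1]:interval[2]]
  h_charge <- if (mode == "acidic") his_protonation_fraction(pH, pKa) else 0
  sum(chars %in% c("K", "R")) - sum(chars %in% c("D", "E")) +
    h_charge * sum(chars == "H")
}

#' Longest run of consecutive histidines in an interval
#'
#' @param sequence amino-acid string.
#' @param interval optional `c(start, end)`; default whole sequence.
#' @return length of the longest maximal H run (0 if none).
#' @export
longest_his_run <- function(sequence, interval = NULL) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (!is.null(interval)) chars <- chars[interval[1]:interval[2]]
  r <- rle(chars == "H")
  if (!any(r$values)) return(0L)
  max(r$lengths[r$values])
}

#' Replace histidines by alanine within an interval
#'
#' Emulates an H-to-A mutant construct: every histidine inside the
#' interval becomes alanine, everything outside is untouched.
#'
#' @param sequence amino-acid string.
#' @param interval `c(start, end)`, 1-based inclusive.
#' @return list with `sequence` (mutant, same length) and `n_replaced`.
#' @export
mutate_his_to_ala <- function(sequence, interval) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (interval[1] < 1 || interval[2] > length(chars) ||
      interval[1] > interval[2])
    stop("invalid interval")
  idx <- interval[1]:interval[2]
  hit <- idx[chars[idx] == "H"]
  chars[hit] <- "A"
  list(sequence = paste(chars, collapse = ""), n_replaced = length(hit))
}

#' Amino-acid composition enrichment of a target over a background pool
#'
#' Per-amino-acid log2 ratio of target frequency to pooled background
#' frequency, with a small pseudo-frequency to keep absent residues
#' finite.
#'
#' @param target amino-acid string (e.g. an IDR).
#' @param background character vector of background sequences, pooled by
#'   concatenation.
#' @param eps pseudo-frequency added to both terms.
#' @return named numeric vector over the 20 standard amino acids.
#' @export
composition_enrichment <- function(target, background, eps = 1e-4) {
  if (!nchar(target)) stop("empty target sequence")
  if (!length(background)) stop("background must be non-empty")
  freq <- function(s) {
    chars <- strsplit(toupper(s), "")[[1]]
    chars <- chars[chars %in% AA_STANDARD]
    tab <- table(factor(chars, levels = AA_STANDARD))
    as.numeric(tab) / max(1L, length(chars))
  }
  ft <- freq(target)
  fb <- freq(paste(background, collapse = ""))
  stats::setNames(log2((ft + eps) / (fb + eps)), AA_STANDARD)
}

#' Screen configuration
#'
#' Bundles every tunable of the candidate-region screen with its default.
#'
#' @param fwhm,span Gaussian kernel parameters, see [make_kernel()].
#' @param charge_threshold strict Delta-charge cutoff for peaks.
#' @param flank residues added on each side of a peak.
#' @param disorder_threshold strict per-side consensus-score cutoff.
#' @param min_peak_separation peak merge distance; defaults to `span`.
#' @param his_weight charge units per histidine (1 = histidine
#'   equivalents; fractional protonation available via
#'   [his_protonation_delta()]).
#' @param expression_min mean-count cutoff for the optional expression
#'   join.
#' @return list of class `ScreenConfig`.
#' @export
screen_config <- function(fwhm = 5, span = 20, charge_threshold = 1,
                          flank = 50, disorder_threshold = 0.3,
                          min_peak_separation = span, his_weight = 1,
                          expression_min = 5) {
  if (charge_threshold <= 0 || flank <= 0 || disorder_threshold <= 0 ||
      min_peak_separation <= 0)
    stop("all thresholds must be positive")
  structure(list(fwhm = fwhm, span = span,
                 charge_threshold = charge_threshold, flank = flank,
                 disorder_threshold = disorder_threshold,
                 min_peak_separation = min_peak_separation,
                 his_weight = his_weight, expression_min = expression_min),
            class = "ScreenConfig")
}

# per-protein disorder score lookup from a sidecar long table
.disorder_lookup <- function(sidecar) {
  sidecar <- sidecar[order(sidecar$protein_id, sidecar$position), ,
                     drop = FALSE]
  split(sidecar[, c("position", "score")], sidecar$protein_id)
}

#' Proteome-wide screen for pH-sensitive candidate regions
#'
#' For every protein: Delta-charge profile, peak calling above the charge
#' threshold, 50-residue flank extension, per-side disorder gating and PQ
#' scoring.  Proteins without disorder information are flagged `unknown`
#' and excluded from the disordered set.  When an expression table is
#' supplied, each candidate gains an `expressed` flag (mean count above
#' `config$expression_min`, matched case-insensitively on accession or
#' gene name).
#'
#' @param proteins a data.frame with columns `accession`, `description`,
#'   `sequence` (see [read_fasta()]), or a path to a FASTA file.
#' @param config a [screen_config()].
#' @param disorder either a sidecar data.frame (`protein_id`, `position`,
#'   `score`), a function `f(sequence) -> scores`, or `NULL`.
#' @param expression optional data.frame with columns `gene_id` and
#'   `mean_count`.
#' @param apply_disorder_gate drop candidates whose region is not
#'   disordered (default, mirroring the published funnel); set `FALSE`
#'   to inspect the pre-gate list.
#' @return data.frame sorted by decreasing Delta-charge (ties: accession,
#'   position) with columns `accession`, `peak_pos`, `delta_charge`,
#'   `start`, `end`, `disorder_n`, `disorder_c`, `disordered`,
#'   `pq_score`, `expressed`, `net_charge`; attribute `"funnel"` counts
#'   survivors of each filter.
#' @export
screen_proteome <- function(proteins, config = screen_config(),
                            disorder = NULL, expression = NULL,
                            apply_disorder_gate = TRUE) {
  if (is.character(proteins) && length(proteins) == 1L)
    proteins <- read_fasta(proteins)
  stopifnot(is.data.frame(proteins),
            all(c("accession", "sequence") %in% names(proteins)))
  kernel <- make_kernel(config$fwhm, config$span)
  sidecar <- NULL
  if (is.data.frame(disorder)) sidecar <- .disorder_lookup(disorder)
  expr_ok <- NULL
  if (!is.null(expression)) {
    expr_ok <- toupper(expression$gene_id[
      expression$mean_count > config$expression_min])
  }
  rows <- list()
  n_peaks <- 0L; n_disordered <- 0L; n_unknown <- 0L
  for (i in seq_len(nrow(proteins))) {
    acc <- proteins$accession[i]
    seqc <- toupper(proteins$sequence[i])
    len <- nchar(seqc)
    if (len == 0L) { warning("empty sequence skipped: ", acc); next }
    prof <- delta_charge_profile(seqc, kernel, config$his_weight)
    peaks <- find_peaks(prof, config$charge_threshold,
                        config$min_peak_separation)
    n_peaks <- n_peaks + length(peaks)
    if (!length(peaks)) next
    scores <- NULL
    if (!is.null(sidecar)) {
      sc <- sidecar[[acc]]
      if (!is.null(sc)) {
        scores <- rep(NA_real_, len)
        ok <- sc$position >= 1 & sc$position <= len
        scores[sc$position[ok]] <- sc$score[ok]
      }
    } else if (is.function(disorder)) {
      scores <- tryCatch(disorder(seqc), error = function(e) {
        warning("disorder predictor failed for ", acc, ": ",
                conditionMessage(e)); NULL })
    }
    for (pk in peaks) {
      region <- extend_region(pk, config$flank, len)
      if (is.null(scores) || anyNA(scores[region[1]:region[2]])) {
        dis <- list(disorder_n = NA_real_, disorder_c = NA_real_,
                    disordered = NA)
        n_unknown <- n_unknown + 1L
      } else {
        dis <- assess_disorder(scores, region, pk,
                               config$disorder_threshold)
        if (isTRUE(dis$disordered)) n_disordered <- n_disordered + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        accession = acc, peak_pos = pk, delta_charge = prof[pk],
        start = region[1], end = region[2],
        disorder_n = dis$disorder_n, disorder_c = dis$disorder_c,
        disordered = dis$disordered,
        pq_score = pq_score(seqc, pk, region, kernel),
        expressed = if (is.null(expr_ok)) NA else toupper(acc) %in% expr_ok,
        net_charge = net_charge(seqc, region),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(accession = character(), peak_pos = integer(),
               delta_charge = numeric(), start = integer(),
               end = integer(), disorder_n = numeric(),
               disorder_c = numeric(), disordered = logical(),
               pq_score = numeric(), expressed = logical(),
               net_charge = numeric(), stringsAsFactors = FALSE)
  if (apply_disorder_gate && nrow(res))
    res <- res[!is.na(res$disordered) & res$disordered, , drop = FALSE]
  if (nrow(res)) {
    res <- res[order(-res$delta_charge, res$accession, res$peak_pos), ,
               drop = FALSE]
    rownames(res) <- NULL
  }
  attr(res, "funnel") <- list(
    n_proteins = nrow(proteins), n_peaks = n_peaks,
    n_disordered = n_disordered, n_disorder_unknown = n_unknown,
    n_reported = nrow(res),
    disorder_gate_applied = apply_disorder_gate)
  res
}
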