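#' Allele fraction from deep-sequencing read counts
#'
#' AF is the binomial maximum-likelihood estimate mutant/total.  A
#' variant is *detected* when its AF reaches the reliable-detection
#' cutoff (default 1% mutated fragments, the amplicon deep-sequencing
#' noise floor without error suppression).
#'
#' @param mutant mutant read count (0 <= mutant <= total).
#' @param total total read count (> 0).
#' @param cutoff detection cutoff on AF (default 0.01).
#' @return list with `af`, `detected`, `cutoff`, `mutant`, `total`.
#' @export
compute_af <- function(mutant, total, cutoff = 0.01) {
  if (any(total <= 0)) stop("total read count must be positive")
  if (any(mutant < 0 | mutant > total)) stop("need 0 <= mutant <= total")
  af <- mutant / total
  list(af = af, detected = af >= cutoff, cutoff = cutoff,
       mutant = mutant, total = total)
}

#' Summarize a set of allele-fraction estimates
#'
#' @param afs numeric vector of AFs, or a list of [compute_af()] results.
#' @param cutoff detection cutoff used for `n_detected` when raw AFs are
#'   given.
#' @return list with `mean`, `sd` (sample standard deviation; NA for a
#'   single estimate), `n`, `n_detected`.
#' @export
summarize_afs <- function(afs, cutoff = 0.01) {
  if (is.list(afs) && !is.null(afs$af)) afs <- list(afs)
  if (is.list(afs)) {
    det <- vapply(afs, function(e) e$detected, logical(1))
    afs <- vapply(afs, function(e) e$af, numeric(1))
  } else {
    det <- afs >= cutoff
  }
  if (length(afs) == 0) stop("no AF estimates supplied")
  list(mean = mean(afs), sd = stats::sd(afs), n = length(afs),
       n_detected = sum(det))
}

#' Total circulating mutant fragments from a per-ml plasma concentration
#'
#' Scales a mutant-fragment concentration (fragments per ml plasma) to a
#' whole-body count using the volume of distribution of circulating DNA,
#' `N_total = per_ml * v * W`, where `v` is the distribution-volume
#' coefficient (ml per kg body weight; oligonucleotide steady-state
#' values in primates are 60-70 ml/kg) and `W` the body weight in kg.
#' Because ctDNA is cleared with a half-life of roughly 16 minutes, the
#' standing total approximates the number of tumor cells that released
#' ctDNA around the time of blood collection; that interpretation is
#' exposed as the `cells_equivalent` alias of `n_total`.
#'
#' @param per_ml mutant fragments per ml plasma (> 0).
#' @param weight_kg body weight in kg (default 60).
#' @param v_ml_per_kg distribution-volume coefficient in ml/kg (default
#'   60, the low end of the primate range).
#' @return list with `per_ml`, `weight_kg`, `v_ml_per_kg`, `n_total`
#'   (exact product), `n_total_2sf` (rounded to 2 significant figures,
#'   round-half-even) and `cells_equivalent` (= `n_total`).
#' @export
total_mutant_fragments <- function(per_ml, weight_kg = 60, v_ml_per_kg = 60) {
  if (any(c(per_ml, weight_kg, v_ml_per_kg) <= 0))
    stop("all arguments must be positive")
  n_total <- per_ml * v_ml_per_kg * weight_kg
  list(per_ml = per_ml, weight_kg = weight_kg, v_ml_per_kg = v_ml_per_kg,
       n_total = n_total, n_total_2sf = signif(n_total, 2),
       cells_equivalent = n_total,
       half_life_min = 16)   # documented clearance constant; not used in math
}
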