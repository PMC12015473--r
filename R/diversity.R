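#' Published reference summary of bud size in a 280-accession tea panel
#'
#' The reported per-trait descriptive and diversity statistics of the four
#' bud size traits in a diverse 280-accession tea germplasm panel
#' (accession-level values; length/width/perimeter in cm, area in cm^2).
#' Used as the reference scale for the simulators and as a magnitude check
#' for the statistics computed here: the exact published binning and
#' heritability formulas are not recoverable, so these values anchor
#' scale, not equality.
#'
#' @return `data.frame` with columns `trait`, `max`, `min`, `mean`, `sd`,
#'   `cv_pct`, `h_prime`, `h2`.
#' @export
reference_trait_table <- function() {
  data.frame(
    trait   = c("length", "width", "perimeter", "area"),
    max     = c(4.91, 0.71, 10.62, 1.48),
    min     = c(1.46, 0.22, 3.23, 0.27),
    mean    = c(2.65, 0.35, 5.75, 0.58),
    sd      = c(0.38, 0.05, 0.83, 0.14),
    cv_pct  = c(14.53, 15.46, 14.45, 24.74),
    h_prime = c(1.97, 1.93, 1.95, 1.95),
    h2      = c(0.72, 0.90, 0.71, 0.60))
}

#' Descriptive statistics for a trait
#'
#' @param values numeric vector of accession-level trait values (at least
#'   2 finite values; mean must be non-zero for the CV).
#' @return A list with `max`, `min`, `mean`, `sd` (sample SD, n-1
#'   denominator) and `cv` (coefficient of variation, `sd/mean * 100`, %).
#' @export
describe_trait <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("need at least 2 finite values")
  m <- mean(values)
  if (m == 0) stop("mean is zero: CV undefined")
  s <- stats::sd(values)
  list(max = max(values), min = min(values), mean = m, sd = s,
       cv = s / m * 100)
}

#' Shannon-Wiener diversity index over trait grading classes
#'
#' Grades a continuous trait into 10 classes anchored at the sample mean
#' and SD — class 1 below `mu - 2*sd`, classes 2-9 in successive `0.5*sd`
#' bands, class 10 above `mu + 2*sd` (the usual germplasm grading
#' convention) — and returns `H' = -sum p_i ln p_i` over the occupied
#' classes (natural log, so the 10-class maximum is `ln 10 ~= 2.303`).
#'
#' @param values numeric vector (>= 2 values).
#' @param n_classes number of grading classes; only the default 10-class
#'   `(mu, sd)`-anchored scheme is implemented.
#' @return `H'` in nats. A zero-variance sample occupies a single class
#'   and returns 0 with a warning.
#' @export
shannon_index <- function(values, n_classes = 10) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("need at least 2 values")
  if (n_classes != 10)
    stop("only the 10-class (mu, sd)-anchored grading scheme is implemented")
  mu <- mean(values); s <- stats::sd(values)
  if (s == 0) {
    warning("zero variance: all values fall in one grading class; H' = 0")
    return(0)
  }
  breaks <- c(-Inf, mu + s * seq(-2, 2, by = 0.5), Inf)
  n_i <- tabulate(cut(values, breaks, labels = FALSE), nbins = n_classes)
  p <- n_i[n_i > 0] / length(values)
  -sum(p * log(p))
}

#' Broad-sense heritability from clonal replicates
#'
#' One-way random-effects variance decomposition with accessions as the
#' random factor and replicate buds within accession as residual:
#' `MS_between` and `MS_within` from the one-way ANOVA, effective
#' replicate number `n0 = (N - sum(n_i^2)/N) / (a - 1)` for unbalanced
#' designs, genetic variance `sigma_g^2 = max(0, (MS_between -
#' MS_within)/n0)`, and `h2 = sigma_g^2 / (sigma_g^2 + MS_within)`.
#'
#' @param values numeric replicate measurements.
#' @param accession factor/character of the accession of each measurement.
#' @return A list with `ms_between`, `ms_within`, `n0`, `sigma2_g` and
#'   `h2` (clipped to `[0, 1]`).
#' @export
broad_sense_heritability <- function(values, accession) {
  stopifnot(length(values) == length(accession))
  ok <- is.finite(values) & !is.na(accession)
  values <- values[ok]
  accession <- factor(accession[ok])
  a <- nlevels(accession)
  if (a < 2) stop("need at least 2 accessions")
  n_i <- as.vector(table(accession))
  if (all(n_i < 2))
    stop("no accession has replicate measurements: ",
         "within-accession variance is inestimable")
  fit <- stats::aov(values ~ accession)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  msb <- ms[1]; msw <- ms[2]
  N <- length(values)
  n0 <- (N - sum(n_i^2) / N) / (a - 1)
  sigma2_g <- max(0, (msb - msw) / n0)
  list(ms_between = msb, ms_within = msw, n0 = n0, sigma2_g = sigma2_g,
       h2 = min(1, sigma2_g / (sigma2_g + msw)))
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around [stats::shapiro.test()] (Royston's algorithm) with
#' the sample-size preconditions made explicit.
#'
#' @param values numeric vector, `3 <= n <= 5000`, non-constant.
#' @return A list with `w` (the W statistic) and `p`.
#' @export
normality_test <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(values) == 0) stop("constant sample: W undefined")
  ht <- stats::shapiro.test(values)
  list(w = unname(ht$statistic), p = ht$p.value)
}

#' Per-trait diversity statistics table
#'
#' Aggregates replicate buds to accession means (arithmetic mean), then
#' computes the descriptive statistics, Shannon-Wiener index and
#' Shapiro-Wilk test on the accession means and broad-sense heritability
#' on the full replicate table — one row per trait, mirroring the usual
#' germplasm summary table.
#'
#' @param phenotypes long-format `data.frame` with columns `accession_id`,
#'   `replicate`, `trait`, `value` (as produced by [simulate_phenotypes()]
#'   or assembled from [extract_features()]).
#' @return `data.frame` with columns `trait`, `max`, `min`, `mean`, `sd`,
#'   `cv_pct`, `h_prime`, `h2`, `shapiro_p`.
#' @export
stats_table <- function(phenotypes) {
  stopifnot(all(c("accession_id", "trait", "value") %in% names(phenotypes)))
  out <- lapply(split(phenotypes, phenotypes$trait), function(d) {
    am <- tapply(d$value, d$accession_id, mean)
    de <- describe_trait(am)
    data.frame(trait = d$trait[1], max = de$max, min = de$min,
               mean = de$mean, sd = de$sd, cv_pct = de$cv,
               h_prime = shannon_index(am),
               h2 = broad_sense_heritability(d$value, d$accession_id)$h2,
               shapiro_p = normality_test(am)$p)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Accession trait means from a replicate phenotype table
#'
#' @param phenotypes long-format table as in [stats_table()], optionally
#'   with a `region` column carried through.
#' @return Wide `data.frame`: `accession_id`, optional `region`, one
#'   column per trait holding the accession mean.
#' @export
accession_means <- function(phenotypes) {
  stopifnot(all(c("accession_id", "trait", "value") %in% names(phenotypes)))
  traits <- unique(phenotypes$trait)
  acc <- unique(phenotypes$accession_id)
  out <- data.frame(accession_id = acc)
  if ("region" %in% names(phenotypes))
    out$region <- phenotypes$region[match(acc, phenotypes$accession_id)]
  for (tr in traits) {
    d <- phenotypes[phenotypes$trait == tr, ]
    m <- tapply(d$value, d$accession_id, mean)
    out[[tr]] <- as.vector(m[acc])
  }
  out
}
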