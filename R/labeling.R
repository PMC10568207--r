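#' Default conversion-model priors
#'
#' Container for the parameters of the two-stage Bayesian conversion model:
#' `eps_s`, the per-base sequencing error rate (default 0.001); `eps_c`, the
#' conversion false-positive rate estimated from unlabeled control cells
#' (default 1.8e-4); `rho`, the sample-level prior probability that an
#' observed mismatch locus is a true conversion; `rho_l`, the 4sU
#' incorporation conversion rate in labeled molecules; and `theta`, the
#' per-gene prior fraction of newly synthesized molecules.
#'
#' @param eps_s Sequencing error rate in \[0,1\].
#' @param eps_c Conversion false-positive rate in \[0,1\].
#' @param rho Sample-level conversion prior in \[0,1\], typically estimated by
#'   [estimate_conversion_prior()].
#' @param rho_l Conversion rate in labeled molecules, typically estimated from
#'   a saturation (long-labeling) experiment by [estimate_rho_l()].
#' @param theta Prior new-molecule fraction; typically per-gene via
#'   [estimate_theta()].
#' @return A list of class `conversion_priors`.
#' @export
conversion_priors <- function(eps_s = 0.001, eps_c = 1.8e-4,
                              rho = NA_real_, rho_l = NA_real_,
                              theta = NA_real_) {
  vals <- c(eps_s = eps_s, eps_c = eps_c, rho = rho, rho_l = rho_l,
            theta = theta)
  bad <- !is.na(vals) & (vals < 0 | vals > 1)
  if (any(bad)) stop("priors must lie in [0, 1]: ", paste(names(vals)[bad], collapse = ", "))
  structure(as.list(vals), class = "conversion_priors")
}

#' Posterior probability that a mismatch locus is a true conversion
#'
#' Two-component binomial mixture: with prior `rho` the locus carries a real
#' T-to-C conversion and each covering read supports it except for sequencing
#' errors (success probability \eqn{1-\epsilon_s}); otherwise the apparent
#' conversions are themselves sequencing errors (success probability
#' \eqn{\epsilon_s}). The posterior
#' \deqn{p_c = \frac{\rho\,B(k; n, 1-\epsilon_s)}
#'   {\rho\,B(k; n, 1-\epsilon_s) + (1-\rho)\,B(k; n, \epsilon_s)}}
#' is computed in log space and is monotone non-decreasing in `k` at fixed `n`.
#'
#' @param k Number of reads supporting the conversion at the locus.
#' @param n Total read depth at the locus (`k <= n`).
#' @param eps_s Sequencing error rate.
#' @param rho Prior conversion probability.
#' @return Posterior probabilities, vectorized over `k`/`n`.
#' @examples
#' conversion_posterior(2, 3, eps_s = 0.001, rho = 0.02)
#' @export
conversion_posterior <- function(k, n, eps_s = 0.001, rho) {
  stopifnot(all(k >= 0), all(n >= 0))
  if (any(k > n)) stop("conversion-supporting reads k cannot exceed depth n")
  stopifnot(eps_s >= 0, eps_s <= 1, rho >= 0, rho <= 1)
  if (rho == 0) return(rep(0, length(k)))
  if (rho == 1) return(rep(1, length(k)))
  l1 <- log(rho) + stats::dbinom(k, n, 1 - eps_s, log = TRUE)
  l2 <- log1p(-rho) + stats::dbinom(k, n, eps_s, log = TRUE)
  out <- 1 / (1 + exp(l2 - l1))
  # l1 = -Inf (impossible under the conversion component) -> posterior 0
  out[is.infinite(l1) & l1 < 0] <- 0
  out
}

#' Estimate the sample-level conversion prior
#'
#' `rho` is the ratio of confidently converted loci (more than half of the
#' covering reads support the conversion) to the total number of observed
#' reference-T positions, pooled over all molecules of the sample.
#'
#' @param molecules Molecule tibble from [merge_reads()] (needs `n_T` and the
#'   `loci` list-column).
#' @param floor Lower clamp applied to the estimate (exact-zero priors would
#'   annihilate all evidence downstream).
#' @return A single probability.
#' @export
estimate_conversion_prior <- function(molecules, floor = 1e-6) {
  stopifnot(nrow(molecules) > 0)
  total_T <- sum(molecules$n_T)
  if (total_T == 0) stop("no observed T positions; cannot estimate rho")
  conf <- sum(vapply(molecules$loci, function(d) {
    if (nrow(d) == 0) 0L else sum(d$k / d$n > 0.5)
  }, integer(1)))
  min(max(conf / total_T, floor), 1 - floor)
}

#' Expected conversion count of a molecule
#'
#' Sums the per-locus conversion posteriors over all mismatch loci of each
#' molecule, giving the (real-valued) expected number of true conversions
#' \eqn{k_m}.
#'
#' @param molecules Molecule tibble with `loci` list-column.
#' @param eps_s Sequencing error rate.
#' @param rho Sample-level conversion prior.
#' @return `molecules` with an added numeric column `km`.
#' @export
molecule_conversion_count <- function(molecules, eps_s = 0.001, rho) {
  molecules$km <- vapply(molecules$loci, function(d) {
    if (nrow(d) == 0) 0 else sum(conversion_posterior(d$k, d$n, eps_s, rho))
  }, numeric(1))
  molecules
}

#' Posterior probability that a molecule is newly synthesized
#'
#' Mixture of a Poisson component for labeled molecules (conversions arrive at
#' rate \eqn{\rho_l} per covered T, so counts are Poisson with mean
#' \eqn{n_m \rho_l}) and a binomial component for preexisting molecules whose
#' apparent conversions are false positives at rate \eqn{\epsilon_c}:
#' \deqn{p_{new} = \frac{\theta\,P(k_m; n_m\rho_l)}
#'   {\theta\,P(k_m; n_m\rho_l) + (1-\theta)\,B(k_m; n_m, \epsilon_c)}.}
#' The expected conversion count `km` is a sum of posteriors and hence real;
#' it is rounded to the nearest integer for pmf evaluation.
#'
#' @param km Expected conversion count(s) of the molecule(s).
#' @param nm Observed reference-T count(s).
#' @param rho_l Conversion rate in labeled molecules.
#' @param eps_c Conversion false-positive rate.
#' @param theta Prior new-molecule fraction.
#' @return Posterior probabilities, vectorized.
#' @examples
#' new_molecule_posterior(3, 50, rho_l = 0.024, eps_c = 1.8e-4, theta = 0.3)
#' @export
new_molecule_posterior <- function(km, nm, rho_l, eps_c = 1.8e-4, theta) {
  if (any(km < 0) || any(nm < 0)) stop("km and nm must be non-negative")
  stopifnot(rho_l >= 0, rho_l <= 1, eps_c >= 0, eps_c <= 1,
            all(theta >= 0), all(theta <= 1))
  k <- round(km)
  l1 <- stats::dpois(k, nm * rho_l, log = TRUE)
  l2 <- stats::dbinom(k, nm, eps_c, log = TRUE)
  # log-space normalized posterior; handle degenerate priors exactly
  out <- 1 / (1 + exp(log1p(-theta) - log(theta) + l2 - l1))
  out[theta == 0] <- 0
  out[theta == 1] <- 1
  # binomial component impossible (k > nm or eps_c = 0 with k > 0):
  # evidence excludes the preexisting component
  imp2 <- is.infinite(l2) & l2 < 0 & theta > 0
  out[imp2] <- 1
  imp1 <- is.infinite(l1) & l1 < 0 & theta < 1
  out[imp1] <- 0
  out
}

#' Per-gene prior fraction of newly synthesized molecules
#'
#' For each gene (optionally within samples), `theta` is the fraction of
#' molecules carrying at least one confident conversion (a locus where more
#' than half of the covering reads support it) among all observed molecules.
#'
#' @param molecules Molecule tibble with `gene` and `loci` columns; an
#'   optional `sample` column groups the estimate per sample.
#' @param floor Optional lower clamp (default 0: a gene with no converted
#'   molecules gets `theta = 0`, hence `pnew = 0` for all its molecules).
#' @return Tibble with `gene` (and `sample` if present) and `theta`.
#' @export
estimate_theta <- function(molecules, floor = 0) {
  stopifnot(nrow(molecules) > 0)
  molecules$converted <- vapply(molecules$loci, function(d) {
    nrow(d) > 0 && any(d$k / d$n > 0.5)
  }, logical(1))
  grp <- if ("sample" %in% names(molecules)) c("gene", "sample") else "gene"
  molecules |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(theta = pmax(mean(.data$converted), floor),
                     .groups = "drop")
}

#' Conversion rate in labeled molecules from a saturation experiment
#'
#' After labeling long enough that essentially every precursor molecule is
#' newly synthesized (e.g. a 24 h incubation), the conversion rate `rho_l` is
#' the pooled ratio of conversions to covered Ts over all precursor
#' molecules. The pooled ratio weights molecules by their T content; setting
#' `method = "per_molecule"` averages per-molecule ratios instead.
#'
#' @param molecules Molecule tibble with columns `n_T` and either a
#'   `conversions` count column or the `loci` list-column (confident loci are
#'   counted as conversions).
#' @param method `"pooled"` (default) or `"per_molecule"`.
#' @return A single rate.
#' @examples
#' m <- tibble::tibble(n_T = c(50, 100), conversions = c(2, 1))
#' estimate_rho_l(m) # 3/150
#' @export
estimate_rho_l <- function(molecules, method = c("pooled", "per_molecule")) {
  method <- match.arg(method)
  stopifnot(nrow(molecules) > 0)
  conv <- if ("conversions" %in% names(molecules)) {
    molecules$conversions
  } else {
    vapply(molecules$loci, function(d) {
      if (nrow(d) == 0) 0L else sum(d$k / d$n > 0.5)
    }, integer(1))
  }
  if (sum(molecules$n_T) == 0) stop("no observed T positions; cannot estimate rho_l")
  if (method == "pooled") {
    sum(conv) / sum(molecules$n_T)
  } else {
    keep <- molecules$n_T > 0
    mean(conv[keep] / molecules$n_T[keep])
  }
}

#' Classify molecules as newly synthesized or preexisting
#'
#' Runs the full per-molecule inference: per-locus conversion posteriors are
#' summed into expected conversion counts, then the Poisson/binomial mixture
#' yields `pnew` per molecule using per-gene priors `theta`.
#'
#' @param molecules Molecule tibble from [merge_reads()].
#' @param priors A [conversion_priors()] object; `rho`, `rho_l` must be set
#'   (estimate them with [estimate_conversion_prior()] / [estimate_rho_l()]).
#' @param theta Optional tibble from [estimate_theta()]; computed from
#'   `molecules` when missing.
#' @return `molecules` with added columns `km`, `theta`, `pnew`.
#' @export
classify_molecules <- function(molecules, priors, theta = NULL) {
  stopifnot(inherits(priors, "conversion_priors"))
  if (is.na(priors$rho) || is.na(priors$rho_l)) {
    stop("priors$rho and priors$rho_l must be set before classification")
  }
  molecules <- molecule_conversion_count(molecules, priors$eps_s, priors$rho)
  if (is.null(theta)) theta <- estimate_theta(molecules)
  molecules <- dplyr::left_join(molecules, theta,
                                by = intersect(names(theta), c("gene", "sample")))
  if (anyNA(molecules$theta)) stop("missing theta for some genes")
  molecules$pnew <- new_molecule_posterior(
    molecules$km, molecules$n_T, priors$rho_l, priors$eps_c, molecules$theta
  )
  molecules
}

#' Assemble the four labeled/unlabeled count matrices
#'
#' Splits each molecule's posterior mass between the labeled and unlabeled
#' matrix of its splice class: a spliced molecule adds `pnew` to the labeled
#' mature matrix `ml` and `1 - pnew` to the unlabeled mature matrix `mu`
#' (precursor matrices `pl`/`pu` for unspliced molecules). Ambiguous
#' molecules contribute nothing. Conservation holds by construction:
#' `pl + pu` is the total precursor count and `ml + mu` the total mature
#' count per gene and cell.
#'
#' @param molecules Classified molecule tibble (needs `pnew`,
#'   `splice_status`, `gene`, `cell_barcode`).
#' @param cells Cell metadata tibble with at least `cell_barcode`; typically
#'   also `phase` (radians) and `labeling_time` (hours). Every molecule's
#'   barcode must be present.
#' @return A `labeled_counts` object: sparse gene-by-cell matrices `pl`,
#'   `ml`, `pu`, `mu` plus the `cells` tibble.
#' @export
assemble_count_matrices <- function(molecules, cells) {
  stopifnot("cell_barcode" %in% names(cells))
  stopifnot(all(c("pnew", "splice_status", "gene", "cell_barcode") %in%
                  names(molecules)))
  missing_bc <- setdiff(unique(molecules$cell_barcode), cells$cell_barcode)
  if (length(missing_bc) > 0) {
    stop("cell barcodes absent from metadata: ",
         paste(utils::head(missing_bc, 5), collapse = ", "))
  }
  mol <- molecules[molecules$splice_status != "ambiguous", ]
  genes <- sort(unique(mol$gene))
  gi <- match(mol$gene, genes)
  ci <- match(mol$cell_barcode, cells$cell_barcode)
  build <- function(rows, w) {
    Matrix::sparseMatrix(
      i = gi[rows], j = ci[rows], x = w,
      dims = c(length(genes), nrow(cells)),
      dimnames = list(genes, cells$cell_barcode)
    )
  }
  spl <- mol$splice_status == "spliced"
  uns <- mol$splice_status == "unspliced"
  labeled_counts(
    pl = build(which(uns), mol$pnew[uns]),
    ml = build(which(spl), mol$pnew[spl]),
    pu = build(which(uns), 1 - mol$pnew[uns]),
    mu = build(which(spl), 1 - mol$pnew[spl]),
    cells = cells
  )
}

#' Labeled/unlabeled precursor and mature count container
#'
#' Bundles the four gene-by-cell matrices (`pl` labeled precursor, `ml`
#' labeled mature, `pu` unlabeled precursor, `mu` unlabeled mature; entries
#' are sums of molecule posteriors, hence non-negative reals) together with
#' per-cell metadata.
#'
#' @param pl,ml,pu,mu Gene-by-cell matrices with identical dimnames.
#' @param cells Tibble of per-cell metadata keyed by `cell_barcode`.
#' @return An object of class `labeled_counts`.
#' @export
labeled_counts <- function(pl, ml, pu, mu, cells) {
  mats <- list(pl = pl, ml = ml, pu = pu, mu = mu)
  dn <- dimnames(mats[[1]])
  for (m in mats) {
    stopifnot(identical(dim(m), dim(mats[[1]])))
  }
  stopifnot(identical(colnames(mats[[1]]), cells$cell_barcode))
  structure(c(mats, list(cells = tibble::as_tibble(cells))),
            class = "labeled_counts")
}

#' @export
print.labeled_counts <- function(x, ...) {
  cat(sprintf("<labeled_counts> %d genes x %d cells (pl, ml, pu, mu)\n",
              nrow(x$pl), ncol(x$pl)))
  invisible(x)
}

#' @rdname labeled_counts
#' @param x A `labeled_counts` object.
#' @param ... Unused.
#' @export
tidy.labeled_counts <- function(x, ...) {
  purrr::map_dfr(c("pl", "ml", "pu", "mu"), function(sp) {
    m <- as(x[[sp]], "TsparseMatrix")
    tibble::tibble(
      species = sp,
      gene = rownames(m)[m@i + 1L],
      cell_barcode = colnames(m)[m@j + 1L],
      count = m@x
    )
  })
}
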