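#' Specify a block-LD synthetic genotype panel
#'
#' Variants are organized in blocks of equicorrelated linkage disequilibrium
#' (LD): dosages of any two variants in the same block have Pearson
#' correlation `within_block_r`, variants in different blocks are
#' independent. One minor-allele frequency (MAF) is drawn per block from
#' `maf_range`, because a single equicorrelated latent factor cannot hit one
#' target dosage correlation across unequal MAFs.
#'
#' @param n_variants total number of variants.
#' @param block_size number of variants per LD block (the last block may be
#'   shorter).
#' @param within_block_r target pairwise dosage correlation inside a block,
#'   in `[0, 1)`.
#' @param maf_range length-2 interval in `(0, 0.5]` from which block MAFs are
#'   drawn.
#' @return an object of class `genotype_block_spec`.
#' @export
genotype_block_spec <- function(n_variants, block_size,
                                within_block_r = 0,
                                maf_range = c(0.05, 0.5)) {
  if (!is_count(n_variants) || !is_count(block_size)) {
    stop_config("n_variants and block_size must be positive integers")
  }
  if (!is.numeric(within_block_r) || within_block_r < 0 || within_block_r >= 1) {
    stop_config("within_block_r must lie in [0, 1)")
  }
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    stop_config("maf_range must be an ordered interval in (0, 0.5]")
  }
  structure(list(n_variants = as.integer(n_variants),
                 block_size = as.integer(block_size),
                 within_block_r = within_block_r,
                 maf_range = as.numeric(maf_range)),
            class = "genotype_block_spec")
}

# P(Z1 > q, Z2 > q) for standard bivariate normal with correlation rho,
# by 1-d quadrature (avoids an extra dependency and is exact to integrate()'s
# tolerance).
bvn_upper_orthant <- function(q, rho) {
  if (abs(rho) < 1e-12) return(stats::pnorm(q, lower.tail = FALSE)^2)
  f <- function(z) {
    stats::dnorm(z) *
      stats::pnorm((rho * z - q) / sqrt(1 - rho^2))
  }
  stats::integrate(f, q, Inf, rel.tol = 1e-10)$value
}

# Latent (tetrachoric) correlation needed so that two Bernoulli(maf)
# threshold indicators have Pearson correlation target_r.
calibrate_latent_r <- function(target_r, maf) {
  if (target_r <= 0) return(0)
  q <- stats::qnorm(1 - maf)
  gap <- function(rho) {
    p11 <- bvn_upper_orthant(q, rho)
    (p11 - maf^2) / (maf * (1 - maf)) - target_r
  }
  stats::uniroot(gap, c(1e-8, 1 - 1e-8), tol = 1e-9)$root
}

#' Generate synthetic genotype dosages with block LD
#'
#' Dosages are sums of two haplotypes; each haplotype allele is a
#' Gaussian-threshold indicator whose latent equicorrelation is calibrated
#' per block so the realized dosage correlation matches
#' `spec$within_block_r`. Column means are approximately `2 * maf`.
#'
#' @param n_individuals number of individuals (rows).
#' @param spec a [genotype_block_spec()].
#' @param seed integer seed.
#' @return an integer matrix (individuals x variants) with values in 0..2 and
#'   an attribute `"map"`: a data.frame with `variant_id`, `chromosome`,
#'   `position_bp`, `block`, `maf`, `effect_allele`, `other_allele`.
#' @export
generate_genotypes <- function(n_individuals, spec, seed = 1L) {
  if (!inherits(spec, "genotype_block_spec")) stop_config("spec must be a genotype_block_spec")
  if (!is_count(n_individuals, min = 2L)) stop_config("n_individuals must be >= 2")
  set.seed(split_seed(seed, 0L))
  m <- spec$n_variants
  block <- rep(seq_len(ceiling(m / spec$block_size)), each = spec$block_size)[seq_len(m)]
  n_block <- max(block)
  maf_block <- stats::runif(n_block, spec$maf_range[1], spec$maf_range[2])

  dos <- matrix(0L, n_individuals, m)
  for (b in seq_len(n_block)) {
    idx <- which(block == b)
    maf <- maf_block[b]
    q <- stats::qnorm(1 - maf)
    rho <- if (length(idx) > 1L) calibrate_latent_r(spec$within_block_r, maf) else 0
    for (hap in 1:2) {
      common <- stats::rnorm(n_individuals)
      z <- sqrt(rho) * common +
        sqrt(1 - rho) * matrix(stats::rnorm(n_individuals * length(idx)),
                               n_individuals, length(idx))
      dos[, idx] <- dos[, idx] + (z > q)
    }
  }
  storage.mode(dos) <- "integer"

  alleles <- c("A", "C", "G", "T")
  ea <- sample(alleles, m, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(alleles, a), 1L), "")
  chrom <- ((block - 1L) %% 22L) + 1L
  pos <- stats::ave(seq_len(m), chrom, FUN = seq_along) * 50000L
  map <- data.frame(variant_id = sprintf("var%05d", seq_len(m)),
                    chromosome = chrom, position_bp = pos, block = block,
                    maf = maf_block[block],
                    effect_allele = ea, other_allele = unname(oa),
                    stringsAsFactors = FALSE)
  colnames(dos) <- map$variant_id
  attr(dos, "map") <- map
  dos
}

#' Score a polygenic score from dosages and a weight table
#'
#' Computes the weighted allele-dosage sum `sum_j w_j d_j` for every
#' individual, reconciling effect alleles against the dosage map: when a
#' weight's effect allele is the panel's other allele, the counted dosage is
#' flipped to `2 - d`. By convention the score is then standardized over all
#' scored individuals (mean 0, sd 1).
#'
#' @param dosages dosage matrix from [generate_genotypes()] (or any matrix
#'   with variant-id column names; allele reconciliation needs the `"map"`
#'   attribute, otherwise weights are assumed pre-aligned).
#' @param weights data.frame with columns `variant_id`, `effect_allele`,
#'   `weight` (a PGS-Catalog-style header `rsID`/`effect_allele`/
#'   `effect_weight` is also accepted via [read_pgs_weights()]).
#' @param standardize if `FALSE`, return the raw weighted sum.
#' @return numeric vector of scores, one per row of `dosages`.
#' @export
score_pgs <- function(dosages, weights, standardize = TRUE) {
  req <- c("variant_id", "effect_allele", "weight")
  if (!all(req %in% names(weights))) {
    stop_config("weights must have columns: ", paste(req, collapse = ", "))
  }
  missing <- setdiff(weights$variant_id, colnames(dosages))
  if (length(missing)) {
    stop_data("weight variants absent from dosages: ",
              paste(missing, collapse = ", "))
  }
  map <- attr(dosages, "map")
  raw <- numeric(nrow(dosages))
  for (i in seq_len(nrow(weights))) {
    vid <- weights$variant_id[i]
    d <- dosages[, vid]
    if (!is.null(map)) {
      row <- map[match(vid, map$variant_id), ]
      if (identical(weights$effect_allele[i], row$other_allele)) {
        d <- 2 - d
      } else if (!identical(weights$effect_allele[i], row$effect_allele)) {
        stop_data("effect allele for ", vid,
                  " matches neither panel allele; cannot reconcile")
      }
    }
    raw <- raw + weights$weight[i] * d
  }
  if (!standardize) return(raw)
  standardize(raw)
}

#' Read / write PGS weight tables
#'
#' Tab-separated `variant_id`, `effect_allele`, `weight`; a PGS-Catalog-style
#' header (`rsID`, `effect_allele`, `effect_weight`, leading `#` comment
#' lines) is tolerated on read.
#'
#' @param path file path (gzip transparent).
#' @return data.frame with the canonical column names.
#' @export
read_pgs_weights <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  nm <- names(tab)
  nm[nm %in% c("rsID", "rsid", "ID")] <- "variant_id"
  nm[nm == "effect_weight"] <- "weight"
  names(tab) <- nm
  req <- c("variant_id", "effect_allele", "weight")
  if (!all(req %in% names(tab))) {
    stop_data("weight file lacks required columns: ",
              paste(setdiff(req, names(tab)), collapse = ", "))
  }
  tab[req]
}

#' @rdname read_pgs_weights
#' @param weights data.frame to write.
#' @export
write_pgs_weights <- function(weights, path) {
  utils::write.table(weights, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
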