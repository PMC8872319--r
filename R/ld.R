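#' Haplotype r-squared between two sites
#'
#' Classical two-locus linkage disequilibrium from phased haplotypes:
#' `D = p_AB - p_A p_B`, `r2 = D^2 / (p_A (1-p_A) p_B (1-p_B))`, computed
#' over pairwise-complete haplotypes. Undefined (NA) when either site is
#' monomorphic among complete haplotypes.
#'
#' @param gm a phased [genotype_matrix()]
#' @param i,j variant indices on the same chromosome.
#' @return r-squared in `[0, 1]`, or `NA`.
#' @export
haplotype_r2 <- function(gm, i, j) {
  if (!gm$phased)
    stop("haplotype r2 requires phased genotypes")
  if (gm$chrom[i] != gm$chrom[j])
    stop("sites must be on the same chromosome")
  x <- gm$haps[, i]; y <- gm$haps[, j]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  pa <- mean(x); pb <- mean(y)
  if (n < 2 || pa %in% c(0, 1) || pb %in% c(0, 1)) return(NA_real_)
  d <- mean(x * y) - pa * pb
  unname(d^2 / (pa * (1 - pa) * pb * (1 - pb)))
}

# All intra-chromosomal site pairs with distance <= max_dist, with r2 computed
# in vectorised chunks (pairwise-complete haplotypes). Pairs are subsampled
# (seeded) to max_pairs to bound runtime. Returns data frame: dist, r2.
pair_r2 <- function(gm, max_dist = 1e6, max_pairs = 2e6, seed = 1L,
                    site_idx = NULL) {
  if (!gm$phased) stop("LD requires phased genotypes")
  if (is.null(site_idx)) site_idx <- seq_len(n_variants(gm))
  ii <- integer(); jj <- integer()
  for (cc in unique(gm$chrom)) {
    idx <- site_idx[gm$chrom[site_idx] == cc]
    p <- gm$pos[idx]
    hi <- findInterval(p + max_dist, p)
    n_per <- hi - seq_along(idx)
    keep <- n_per > 0
    if (!any(keep)) next
    ii <- c(ii, idx[rep(which(keep), n_per[keep])])
    jj <- c(jj, idx[unlist(lapply(which(keep), function(a)
      seq(a + 1L, hi[a])))])
  }
  if (!length(ii)) stop("no intra-chromosomal site pairs within max_dist")
  if (length(ii) > max_pairs) {
    set.seed(seed)
    sel <- sample.int(length(ii), max_pairs)
    ii <- ii[sel]; jj <- jj[sel]
  }
  H <- gm$haps
  r2 <- numeric(length(ii))
  chunk <- 100000L
  for (off in seq(0L, length(ii) - 1L, by = chunk)) {
    sel <- seq(off + 1L, min(off + chunk, length(ii)))
    X <- H[, ii[sel], drop = FALSE]
    Y <- H[, jj[sel], drop = FALSE]
    M <- (!is.na(X)) & (!is.na(Y))
    X0 <- X; Y0 <- Y
    X0[!M] <- 0L; Y0[!M] <- 0L
    n <- colSums(M)
    sx <- colSums(X0); sy <- colSums(Y0); sxy <- colSums(X0 * Y0)
    num <- (n * sxy - sx * sy)^2
    den <- (n * sx - sx^2) * (n * sy - sy^2)
    r2[sel] <- ifelse(den > 0 & n >= 2, num / den, NA_real_)
  }
  data.frame(dist = abs(gm$pos[jj] - gm$pos[ii]), r2 = r2)
}

#' LD decay profile
#'
#' Bins all intra-chromosomal pairs within `max_dist` by distance and reports
#' mean r-squared per bin. The decay distance is the upper edge of the first
#' bin (scanning from distance zero) whose mean r2 is below `r2_threshold`
#' and that is not followed by any bin at or above the threshold within the
#' next 5 bins (a smoothing guard); `Inf` when no such bin exists.
#'
#' @param gm a phased [genotype_matrix()]
#' @param max_dist maximum pair distance (bp).
#' @param bin_width distance bin width (bp).
#' @param r2_threshold decay threshold on mean r2.
#' @param max_pairs pair subsample cap.
#' @param seed subsampling seed.
#' @return data frame (bin_start, bin_end, n_pairs, mean_r2) with attribute
#'   `"decay_distance"`.
#' @export
ld_decay <- function(gm, max_dist = 1e6, bin_width = 1e4, r2_threshold = 0.2,
                     max_pairs = 2e6, seed = 1L) {
  pr <- pair_r2(gm, max_dist = max_dist, max_pairs = max_pairs, seed = seed)
  edges <- seq(0, max_dist, by = bin_width)
  if (edges[length(edges)] < max_dist) edges <- c(edges, max_dist)
  bin <- findInterval(pr$dist, edges, left.open = TRUE, all.inside = TRUE)
  n_bins <- length(edges) - 1L
  tab <- data.frame(bin_start = edges[-length(edges)], bin_end = edges[-1],
                    n_pairs = tabulate(bin, n_bins), mean_r2 = NA_real_)
  ok <- !is.na(pr$r2)
  if (any(ok)) {
    m <- rowsum(pr$r2[ok], bin[ok])
    cnt <- rowsum(rep(1, sum(ok)), bin[ok])
    tab$mean_r2[as.integer(rownames(m))] <- m / cnt
  }
  below <- !is.na(tab$mean_r2) & tab$mean_r2 < r2_threshold
  at_or_above <- !is.na(tab$mean_r2) & tab$mean_r2 >= r2_threshold
  decay <- Inf
  for (b in seq_len(n_bins)) {
    if (below[b]) {
      guard <- seq(b + 1L, min(b + 5L, n_bins))
      if (b == n_bins || !any(at_or_above[guard])) {
        decay <- tab$bin_end[b]
        break
      }
    }
  }
  attr(tab, "decay_distance") <- decay
  tab
}

# Mapping functions from genetic distance d (Morgans) to recombination rate c.
# The exact closed form of the Sved mapping used by SNeP's "svedf" is not
# restatable here; "sved" aliases Haldane with a one-time warning.
map_distance <- function(d, mapping = c("sved", "haldane", "linear")) {
  mapping <- match.arg(mapping)
  switch(mapping,
         linear = d,
         haldane = 0.5 * (1 - exp(-2 * d)),
         sved = 0.5 * (1 - exp(-2 * d)))
}

#' LD-based historical effective population size
#'
#' Bins site pairs by physical distance and, per bin, converts the mean
#' distance to a recombination rate `c` via a mapping function (1 cM/Mb),
#' applies the finite-sample correction `E[r2_adj] = mean r2 - 1/(2*n)`
#' (`correction = "2n"`, chromosome-based alternative `"n"`), and inverts
#' Sved's expectation `E[r2] = 1/(alpha + 4*Ne*c)`:
#' `Ne = (1/(4c)) * (1/E[r2_adj] - alpha)`, dated `t = 1/(2c)` generations
#' ago.
#'
#' @param gm a phased [genotype_matrix()]
#' @param bins number of equal-width distance bins over `(0, max_dist]`.
#' @param mapping `"sved"`, `"haldane"` or `"linear"`.
#' @param mutation_alpha alpha in Sved's formula (2.2 mutation-adjusted, or 1).
#' @param max_dist maximum pair distance (bp).
#' @param min_maf minimum minor allele frequency of sites entering pairs.
#' @param correction `"2n"` (1/(2n), diploid-sample convention) or `"n"`.
#' @param min_pairs minimum pairs per usable bin.
#' @param max_pairs pair subsample cap.
#' @param seed subsampling seed.
#' @return data frame: bin, mean_dist, c, mean_r2, r2_adj, ne, t (bins where
#'   the inversion is undefined carry `NA` ne/t).
#' @export
estimate_ne <- function(gm, bins = 20, mapping = "sved", mutation_alpha = 2.2,
                        max_dist = 1e6, min_maf = 0.05,
                        correction = c("2n", "n"), min_pairs = 100,
                        max_pairs = 2e6, seed = 1L) {
  correction <- match.arg(correction)
  ac <- allele_counts(gm)
  af <- ifelse(ac$n > 0, ac$alt / ac$n, 0)
  site_idx <- which(pmin(af, 1 - af) >= min_maf)
  pr <- pair_r2(gm, max_dist = max_dist, max_pairs = max_pairs, seed = seed,
                site_idx = site_idx)
  corr <- if (correction == "2n") 1 / (2 * n_samples(gm))
          else 1 / n_samples(gm)
  ne_from_pairs(pr$dist, pr$r2, bins = bins, mapping = mapping,
                mutation_alpha = mutation_alpha, max_dist = max_dist,
                sample_correction = corr, min_pairs = min_pairs)
}

#' Ne trajectory from precomputed pair distances and r-squared values
#'
#' Lower-level workhorse behind [estimate_ne()]; useful for parameter-recovery
#' checks where r2 values are generated directly from the model
#' `E[r2] = 1/(alpha + 4*Ne*c) + correction`.
#'
#' @param dist pair distances (bp).
#' @param r2 pair r-squared values (NA allowed).
#' @param bins,mapping,mutation_alpha,max_dist,min_pairs see [estimate_ne()].
#' @param sample_correction the additive finite-sample term subtracted from
#'   each bin's mean r2.
#' @return see [estimate_ne()].
#' @export
ne_from_pairs <- function(dist, r2, bins = 20, mapping = "sved",
                          mutation_alpha = 2.2, max_dist = max(dist),
                          sample_correction = 0, min_pairs = 100) {
  mapping <- match.arg(mapping, c("sved", "haldane", "linear"))
  if (mapping == "sved") {
    warning("'sved' mapping aliases Haldane (exact Sved closed form ",
            "unavailable); use mapping='haldane' to silence", call. = FALSE)
    mapping <- "haldane"
  }
  ok <- !is.na(r2) & dist > 0 & dist <= max_dist
  dist <- dist[ok]; r2 <- r2[ok]
  if (length(dist) < 2 * min_pairs)
    stop("not enough informative pairs for Ne estimation")
  edges <- seq(0, max_dist, length.out = bins + 1)
  bin <- findInterval(dist, edges, left.open = TRUE, all.inside = TRUE)
  out <- data.frame(bin = seq_len(bins),
                    bin_start = edges[-length(edges)], bin_end = edges[-1],
                    n_pairs = tabulate(bin, bins),
                    mean_dist = NA_real_, c = NA_real_, mean_r2 = NA_real_,
                    r2_adj = NA_real_, ne = NA_real_, t = NA_real_)
  for (b in seq_len(bins)) {
    sel <- bin == b
    if (sum(sel) < min_pairs) next
    d_bp <- mean(dist[sel])
    d_m <- d_bp * 1e-8                     # 1 cM/Mb => Morgans
    cc <- map_distance(d_m, mapping)
    mr2 <- mean(r2[sel])
    adj <- mr2 - sample_correction
    out$mean_dist[b] <- d_bp
    out$c[b] <- cc
    out$mean_r2[b] <- mr2
    out$r2_adj[b] <- adj
    if (adj > 0) {
      ne <- (1 / (4 * cc)) * (1 / adj - mutation_alpha)
      if (is.finite(ne) && ne > 0) {
        out$ne[b] <- ne
        out$t[b] <- 1 / (2 * cc)
      }
    }
  }
  out
}
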