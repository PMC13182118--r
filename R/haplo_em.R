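#' Enumerate haplotype pairs compatible with a diploid genotype
#'
#' For a vector of biallelic genotypes coded as alt-allele dosages (0, 1, 2),
#' lists every unordered haplotype pair that explains the genotype. With k
#' heterozygous sites there are `2^(k-1)` pairs (one pair when k is 0 or 1).
#' Haplotypes are returned as strings of 0/1 alleles in site order.
#'
#' @param genotype integer vector of dosages in 0,1,2 (no missing values).
#' @param het_cap maximum number of heterozygous sites before enumeration is
#'   refused (default 20).
#' @return a list of length-2 character vectors `c(h1, h2)` with `h1 <= h2`
#'   lexicographically.
#' @export
enumerate_pairs <- function(genotype, het_cap = 20) {
  if (anyNA(genotype)) stop("missing genotypes not allowed", call. = FALSE)
  if (!all(genotype %in% 0:2)) stop("dosages must be 0, 1 or 2", call. = FALSE)
  het <- which(genotype == 1L)
  k <- length(het)
  if (k > het_cap)
    stop(sprintf("%d heterozygous sites exceeds the enumeration cap (%d)",
                 k, het_cap), call. = FALSE)
  base <- ifelse(genotype == 2L, "1", "0")
  if (k == 0) {
    h <- paste(base, collapse = "")
    return(list(c(h, h)))
  }
  # fix the first het site to 0 on h1: enumerates unordered pairs once
  n_free <- k - 1L
  out <- vector("list", 2^n_free)
  for (m in seq_len(2^n_free) - 1L) {
    h1 <- base; h2 <- base
    h1[het[1]] <- "0"; h2[het[1]] <- "1"
    if (n_free > 0) {
      bits <- as.integer(intToBits(m))[seq_len(n_free)]
      h1[het[-1]] <- as.character(bits)
      h2[het[-1]] <- as.character(1L - bits)
    }
    pair <- sort(c(paste(h1, collapse = ""), paste(h2, collapse = "")))
    out[[m + 1L]] <- pair
  }
  out
}

# internal: group complete-case genotype rows and precompute pair structures
build_em_structures <- function(geno, het_cap) {
  keys <- apply(geno, 1, paste, collapse = ",")
  uk <- unique(keys)
  groups <- lapply(uk, function(k) which(keys == k))
  counts <- vapply(groups, length, integer(1))
  pair_list <- lapply(uk, function(k) {
    g <- as.integer(strsplit(k, ",")[[1]])
    enumerate_pairs(g, het_cap = het_cap)
  })
  haps <- sort(unique(unlist(pair_list)))
  pair_idx <- lapply(pair_list, function(pl) {
    cbind(i1 = match(vapply(pl, `[`, character(1), 1), haps),
          i2 = match(vapply(pl, `[`, character(1), 2), haps))
  })
  list(haps = haps, groups = groups, counts = counts, pair_idx = pair_idx,
       keys = keys, unique_keys = uk)
}

#' Estimate haplotype frequencies from unphased genotypes by EM
#'
#' Fits population haplotype frequencies to unphased multilocus diploid
#' genotypes by expectation-maximization (the gene-counting EM of
#' Excoffier-Slatkin type used for haplotype reconstruction when phase is
#' unknown). Each individual's genotype is explained by the set of haplotype
#' pairs compatible with it; the E-step weights pair (h1, h2) by
#' `2 f_h1 f_h2` (or `f_h^2` when homozygous) normalized within the
#' individual, and the M-step sets each frequency to its expected haplotype
#' count divided by the number of chromosomes.
#'
#' Initialization is uniform over the haplotypes compatible with at least
#' one observed genotype, making the fit deterministic. Individuals with any
#' missing genotype at the selected sites are excluded and counted.
#'
#' @param geno integer matrix (individuals x sites) of alt-allele dosages
#'   0/1/2, `NA` for missing; column order defines haplotype string order.
#' @param tol convergence tolerance on the largest absolute frequency change
#'   per iteration (default 1e-8).
#' @param max_iter maximum EM iterations (default 1000).
#' @param init optional named numeric vector of starting frequencies (e.g. a
#'   cohort-level fit used to initialize a within-breed fit); haplotypes not
#'   named get a small positive mass before renormalization.
#' @param sites optional data.frame of per-site metadata (carried through to
#'   downstream translation).
#' @param het_cap maximum heterozygous sites per individual (default 20).
#' @return an object of class `haplo_em` with components `frequencies`
#'   (named, summing to 1), `loglik`, `loglik_trace`, `iterations`,
#'   `converged`, `n_ind`, `n_chrom`, `n_excluded`, and the complete-case
#'   genotypes used.
#' @seealso [predict.haplo_em()] for most-probable pair assignment,
#'   [simulate.haplo_em()] for generating genotypes from the fit.
#' @examples
#' g <- rbind(a = c(0L, 0L), b = c(1L, 1L))  # one hom-ref, one double-het
#' fit <- haplo_em(g)
#' coef(fit)  # 00 -> 0.75, 11 -> 0.25
#' @export
haplo_em <- function(geno, tol = 1e-8, max_iter = 1000, init = NULL,
                     sites = NULL, het_cap = 20) {
  geno <- as.matrix(geno)
  if (is.null(rownames(geno)))
    rownames(geno) <- sprintf("ind%d", seq_len(nrow(geno)))
  complete <- stats::complete.cases(geno)
  n_excluded <- sum(!complete)
  geno_cc <- geno[complete, , drop = FALSE]
  if (nrow(geno_cc) == 0)
    stop("no individuals with complete genotypes", call. = FALSE)
  st <- build_em_structures(geno_cc, het_cap)
  H <- length(st$haps)
  N <- nrow(geno_cc)
  n_chrom <- 2L * N

  if (is.null(init)) {
    f <- rep(1 / H, H)
  } else {
    f <- rep(1e-6, H)
    hit <- match(st$haps, names(init))
    f[!is.na(hit)] <- f[!is.na(hit)] + init[hit[!is.na(hit)]]
    f <- f / sum(f)
  }
  names(f) <- st$haps

  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    counts <- numeric(H)
    ll <- 0
    for (g in seq_along(st$unique_keys)) {
      pi <- st$pair_idx[[g]]
      mult <- ifelse(pi[, 1] == pi[, 2], 1, 2)
      w <- mult * f[pi[, 1]] * f[pi[, 2]]
      lik <- sum(w)
      ll <- ll + st$counts[g] * log(lik)
      post <- w / lik
      add <- st$counts[g] * post
      for (p in seq_len(nrow(pi))) {
        counts[pi[p, 1]] <- counts[pi[p, 1]] + add[p]
        counts[pi[p, 2]] <- counts[pi[p, 2]] + add[p]
      }
    }
    trace <- c(trace, ll)
    f_new <- counts / n_chrom
    names(f_new) <- st$haps
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }

  structure(list(
    frequencies = f, haplotypes = st$haps,
    loglik = trace[length(trace)], loglik_trace = trace,
    iterations = iter, converged = converged,
    n_ind = N, n_chrom = n_chrom, n_excluded = n_excluded,
    geno = geno_cc, sites = sites, tol = tol, het_cap = het_cap,
    call = match.call()
  ), class = "haplo_em")
}

#' @export
#' @method print haplo_em
print.haplo_em <- function(x, digits = 4, ...) {
  cat(sprintf(
    "<haplo_em> %d haplotypes over %d sites; %d individuals (%d chromosomes)\n",
    length(x$frequencies), nchar(x$haplotypes[1]), x$n_ind, x$n_chrom))
  cat(sprintf("  %s after %d iterations; log-likelihood %.4f\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$loglik))
  f <- sort(x$frequencies, decreasing = TRUE)
  f <- f[f > 0]
  print(round(utils::head(f, 10), digits))
  if (length(f) > 10) cat("  ...\n")
  invisible(x)
}

#' @export
#' @method coef haplo_em
coef.haplo_em <- function(object, ...) object$frequencies

#' @export
#' @method logLik haplo_em
logLik.haplo_em <- function(object, ...) {
  structure(object$loglik, df = length(object$frequencies) - 1L,
            nobs = object$n_ind, class = "logLik")
}

#' @rdname haplo_em
#' @param object,x a fitted `haplo_em` object.
#' @param ... unused.
#' @export
#' @method summary haplo_em
summary.haplo_em <- function(object, ...) {
  f <- object$frequencies
  tab <- data.frame(
    haplotype = names(f), frequency = unname(f),
    expected_copies = unname(f) * object$n_chrom,
    sub_singleton = unname(f) > 0 & unname(f) < 1 / (2 * object$n_chrom),
    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$frequency, tab$haplotype), ]
  rownames(tab) <- NULL
  out <- list(table = tab, converged = object$converged,
              iterations = object$iterations, loglik = object$loglik,
              n_ind = object$n_ind, n_excluded = object$n_excluded)
  class(out) <- "summary.haplo_em"
  out
}

#' @export
#' @method print summary.haplo_em
print.summary.haplo_em <- function(x, digits = 4, ...) {
  cat(sprintf("Haplotype frequency estimate (%d individuals, %d excluded)\n",
              x$n_ind, x$n_excluded))
  cat(sprintf("%s in %d iterations; log-likelihood %.4f\n",
              if (x$converged) "Converged" else "Did not converge",
              x$iterations, x$loglik))
  tab <- x$table
  tab$frequency <- round(tab$frequency, digits)
  tab$expected_copies <- round(tab$expected_copies, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Most-probable haplotype pair per individual
#'
#' Computes, for each individual, the posterior distribution over compatible
#' haplotype pairs under the fitted frequencies and reports the most
#' probable pair (ties broken lexicographically by haplotype string).
#'
#' @param object a fitted `haplo_em`.
#' @param newdata optional dosage matrix; defaults to the fitting data.
#'   Haplotypes unseen at fit time have frequency 0.
#' @param type `"pairs"` (default) for the argmax assignment table, or
#'   `"posterior"` for the full per-individual posterior.
#' @param ... unused.
#' @return for `"pairs"`, a data.frame with `id`, `hap1`, `hap2`,
#'   `posterior`; for `"posterior"`, a named list of data.frames.
#' @export
predict.haplo_em <- function(object, newdata = NULL,
                             type = c("pairs", "posterior"), ...) {
  type <- match.arg(type)
  geno <- if (is.null(newdata)) object$geno else as.matrix(newdata)
  if (is.null(rownames(geno)))
    rownames(geno) <- sprintf("ind%d", seq_len(nrow(geno)))
  f <- object$frequencies
  get_f <- function(h) ifelse(is.na(match(h, names(f))), 0, f[match(h, names(f))])
  posts <- lapply(seq_len(nrow(geno)), function(i) {
    pl <- enumerate_pairs(geno[i, ], het_cap = object$het_cap)
    h1 <- vapply(pl, `[`, character(1), 1)
    h2 <- vapply(pl, `[`, character(1), 2)
    mult <- ifelse(h1 == h2, 1, 2)
    w <- mult * get_f(h1) * get_f(h2)
    tot <- sum(w)
    post <- if (tot > 0) w / tot else rep(1 / length(w), length(w))
    d <- data.frame(hap1 = h1, hap2 = h2, posterior = post,
                    stringsAsFactors = FALSE)
    d[order(-d$posterior, d$hap1, d$hap2), , drop = FALSE]
  })
  names(posts) <- rownames(geno)
  if (type == "posterior") return(posts)
  best <- do.call(rbind, lapply(posts, function(d) d[1, , drop = FALSE]))
  data.frame(id = rownames(geno), best, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Simulate genotypes from fitted haplotype frequencies
#'
#' Draws diploid individuals by sampling two haplotypes independently from
#' the fitted frequency distribution (Hardy-Weinberg pairing) and returns
#' dosage matrices.
#'
#' @param object a fitted `haplo_em`.
#' @param nsim number of replicate matrices.
#' @param seed optional integer seed.
#' @param n individuals per replicate (default: as fitted).
#' @param ... unused.
#' @return a list of `nsim` dosage matrices with a `haplotypes` attribute
#'   recording the sampled pair per individual.
#' @export
simulate.haplo_em <- function(object, nsim = 1, seed = NULL,
                              n = object$n_ind, ...) {
  if (!is.null(seed)) set.seed(seed)
  f <- object$frequencies
  haps <- names(f)
  lapply(seq_len(nsim), function(s) {
    h1 <- sample(haps, n, replace = TRUE, prob = f)
    h2 <- sample(haps, n, replace = TRUE, prob = f)
    g <- hap_strings_to_dosage(h1, h2)
    rownames(g) <- sprintf("sim%d", seq_len(n))
    attr(g, "haplotypes") <- data.frame(hap1 = pmin(h1, h2),
                                        hap2 = pmax(h1, h2),
                                        stringsAsFactors = FALSE)
    g
  })
}

hap_strings_to_dosage <- function(h1, h2) {
  a1 <- do.call(rbind, lapply(strsplit(h1, ""), as.integer))
  a2 <- do.call(rbind, lapply(strsplit(h2, ""), as.integer))
  a1 + a2
}

#' Fit haplotype frequencies for the cohort and within each breed
#'
#' Runs the EM on the full cohort first, then separately within each breed,
#' initializing each breed-level fit from the cohort frequencies (this
#' stabilizes small breeds without changing the fixed point reached on
#' well-determined data). Breeds below `min_animals` individuals with
#' complete genotypes are skipped with a warning.
#'
#' @param geno dosage matrix (individuals x sites).
#' @param breed breed label per individual (row).
#' @param min_animals minimum complete-genotype individuals per breed
#'   (default 2).
#' @param ... passed to [haplo_em()].
#' @return list with `cohort` (a `haplo_em`) and `breeds` (named list of
#'   `haplo_em` fits).
#' @export
haplo_em_by_breed <- function(geno, breed, min_animals = 2, ...) {
  geno <- as.matrix(geno)
  stopifnot(length(breed) == nrow(geno))
  cohort <- haplo_em(geno, ...)
  fits <- list()
  for (b in unique(breed)) {
    sub <- geno[breed == b, , drop = FALSE]
    n_complete <- sum(stats::complete.cases(sub))
    if (n_complete < min_animals) {
      warning(sprintf("breed %s: only %d complete individuals; skipped",
                      b, n_complete), call. = FALSE)
      next
    }
    fits[[b]] <- haplo_em(sub, init = cohort$frequencies, ...)
  }
  list(cohort = cohort, breeds = fits)
}
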