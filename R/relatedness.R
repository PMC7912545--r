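#' Inbreeding coefficients by the Meuwissen-Luo algorithm
#'
#' Computes each animal's inbreeding coefficient F (the probability that its
#' two alleles at a locus are identical by descent) as the diagonal of the
#' numerator relationship matrix minus one, using the Meuwissen-Luo
#' L-and-D traversal: for every animal only the vector of path coefficients
#' over its own ancestors is held, never a dense matrix. Animals sharing the
#' same (sire, dam) pair reuse the computed value.
#'
#' @param ped A `pedigree`.
#' @return Numeric vector of F, one per record, in pedigree order, named by
#'   id.
#' @export
inbreeding <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  si <- ped$sire_idx; di <- ped$dam_idx
  Fv <- numeric(n)
  # Mendelian sampling variance with F(unknown parent) = -1 convention
  Ds <- numeric(n)
  L <- numeric(n)        # scratch path coefficients
  seen_pair <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    fs <- if (s > 0) Fv[s] else -1
    fd <- if (d > 0) Fv[d] else -1
    Ds[i] <- 0.5 - 0.25 * (fs + fd)
    if (s == 0 || d == 0) { Fv[i] <- 0; next }
    key <- paste0(s, "_", d)
    hit <- seen_pair[[key]]
    if (!is.null(hit)) { Fv[i] <- hit; next }
    # ancestors of i (including i), visited from the youngest down so each
    # animal's L is final before its own parents receive mass
    anc <- integer(0)
    inset <- logical(i)
    stack <- i; inset[i] <- TRUE
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      anc[length(anc) + 1L] <- v
      for (p in c(si[v], di[v])) {
        if (p > 0 && !inset[p]) { inset[p] <- TRUE; stack <- c(stack, p) }
      }
    }
    anc <- sort.int(anc, decreasing = TRUE)
    L[anc] <- 0; L[i] <- 1
    acc <- 0
    for (j in anc) {
      lj <- L[j]
      acc <- acc + lj * lj * Ds[j]
      sj <- si[j]; dj <- di[j]
      if (sj > 0) L[sj] <- L[sj] + lj / 2
      if (dj > 0) L[dj] <- L[dj] + lj / 2
    }
    Fv[i] <- acc - 1
    seen_pair[[key]] <- Fv[i]
  }
  names(Fv) <- ped$id
  Fv
}

# Mendelian sampling variances D_i given F; unknown-parent terms drop out of
# var(mendelian sampling): both known 0.5-0.25(Fs+Fd); one known
# 0.75-0.25Fk; founder 1.
mendelian_variance <- function(ped, F = inbreeding(ped)) {
  s <- ped$sire_idx; d <- ped$dam_idx
  fs <- ifelse(s > 0, F[pmax(s, 1)], -1)
  fd <- ifelse(d > 0, F[pmax(d, 1)], -1)
  0.5 - 0.25 * (fs + fd)
}

#' Indirect relationship-matrix product A x
#'
#' Computes `A %*% x` without forming the additive relationship matrix A,
#' via the Colleau decomposition A = T D T' (T the gene-flow matrix, D the
#' diagonal of Mendelian sampling variances): one backward and one forward
#' sweep over the topologically ordered pedigree, linear in records per
#' column of `x`.
#'
#' @param ped A `pedigree`.
#' @param x Numeric vector of length `nrow(ped)`, or a matrix with that many
#'   rows.
#' @param F Precomputed inbreeding vector (optional).
#' @return `A %*% x`, same shape as `x`.
#' @export
relationship_product <- function(ped, x, F = NULL) {
  n <- nrow(ped)
  x <- as.matrix(x)
  stopifnot(nrow(x) == n)
  if (is.null(F)) F <- inbreeding(ped)
  D <- mendelian_variance(ped, F)
  si <- ped$sire_idx; di <- ped$dam_idx
  u <- x
  for (i in n:1) {
    s <- si[i]; d <- di[i]
    if (s > 0) u[s, ] <- u[s, ] + 0.5 * u[i, ]
    if (d > 0) u[d, ] <- u[d, ] + 0.5 * u[i, ]
  }
  v <- u * D
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (s > 0) v[i, ] <- v[i, ] + 0.5 * v[s, ]
    if (d > 0) v[i, ] <- v[i, ] + 0.5 * v[d, ]
  }
  if (ncol(v) == 1) drop(v) else v
}

#' Pairwise coancestry coefficients
#'
#' Coancestry (kinship) f_xy = a_xy / 2, with self-coancestry
#' f_xx = (1 + F_x) / 2. Computed column-wise through
#' [relationship_product()], so no dense relationship matrix is built.
#'
#' @param ped A `pedigree`.
#' @param ids1,ids2 Character vectors of ids; the result is the
#'   `length(ids1)` x `length(ids2)` coancestry matrix. `ids2` defaults to
#'   `ids1`.
#' @return Numeric matrix of coancestries.
#' @export
coancestry <- function(ped, ids1, ids2 = ids1) {
  i1 <- focal_indices(ped, ids1)
  i2 <- focal_indices(ped, ids2)
  F <- inbreeding(ped)
  X <- matrix(0, nrow(ped), length(i2))
  X[cbind(i2, seq_along(i2))] <- 1
  A2 <- relationship_product(ped, X, F)
  out <- as.matrix(A2)[i1, , drop = FALSE] / 2
  dimnames(out) <- list(ped$id[i1], ped$id[i2])
  out
}

#' Exact mean coancestry of a reference set
#'
#' Mean of f over all ordered pairs of the reference, self-pairs included
#' (so a set of n unrelated non-inbred founders has mean 1/(2n)). Computed
#' as x'Ax/2 with x the uniform weight vector, through the indirect product.
#'
#' @param ped A `pedigree`.
#' @param reference Ids of the reference set (defaults to the focal set,
#'   else all records).
#' @param F Precomputed inbreeding vector (optional).
#' @param include_self Include self-pairs (default). Exclude them when the
#'   mean is meant to describe coancestry between potential mates, e.g. for
#'   mating-system (alpha-type) comparisons, where the self term
#'   (1 + F)/2 adds an O(1/n) upward bias.
#' @export
mean_coancestry <- function(ped, reference = NULL, F = NULL,
                            include_self = TRUE) {
  idx <- focal_indices(ped, reference)
  x <- numeric(nrow(ped))
  x[idx] <- 1 / length(idx)
  if (is.null(F)) F <- inbreeding(ped)
  cbar <- sum(x * relationship_product(ped, x, F)) / 2
  if (include_self) return(cbar)
  m <- length(idx)
  if (m < 2) stop("need at least two reference animals to exclude self-pairs")
  (m^2 * cbar - sum((1 + F[idx]) / 2)) / (m^2 - m)
}

#' Average relatedness
#'
#' AR_i is the mean additive relationship of animal i with every animal in
#' the pedigree, itself included: the i-th entry of A 1/n, computed
#' indirectly in linear time.
#'
#' @param ped A `pedigree`.
#' @param F Precomputed inbreeding vector (optional).
#' @return Named numeric vector of AR in pedigree order.
#' @export
average_relatedness <- function(ped, F = NULL) {
  n <- nrow(ped)
  ar <- relationship_product(ped, rep(1 / n, n), F)
  names(ar) <- ped$id
  ar
}

#' Individual rate of inbreeding
#'
#' The per-generation rate implied by an individual's F over its realized
#' pedigree depth t (equivalent generations):
#' `dF = 1 - (1 - F)^(1/(t - 1))`. For t <= 1 only one generation is
#' observed and the rate is taken to be F itself.
#'
#' @param F Inbreeding coefficient(s), in `[0, 1)`.
#' @param t Equivalent generations, same length or scalar.
#' @return Rate(s) of inbreeding.
#' @export
rate_of_inbreeding <- function(F, t) {
  if (any(F >= 1)) stop("F must be < 1")
  if (any(F < 0)) stop("F must be >= 0")
  out <- ifelse(t > 1, 1 - (1 - F)^(1 / (t - 1)), F)
  out
}

#' Pairwise rate of coancestry
#'
#' `dC = 1 - (1 - f_ab)^(1/((t_a + t_b)/2))`, symmetric in the pair.
#'
#' @param f_ab Coancestry of the pair.
#' @param t_a,t_b Equivalent generations of each member.
#' @export
rate_of_coancestry <- function(f_ab, t_a, t_b) {
  if (any(f_ab >= 1)) stop("coancestry must be < 1")
  tbar <- (t_a + t_b) / 2
  if (any(tbar <= 0)) stop("mean equivalent generations must be > 0")
  1 - (1 - f_ab)^(1 / tbar)
}

#' Mean rate of coancestry over a reference set
#'
#' Averages [rate_of_coancestry()] over pairs of distinct reference animals.
#' All pairs are used up to `max_exact` reference animals; above that a
#' seeded random sample of `n_pairs` pairs is taken.
#'
#' @param ped A `pedigree`.
#' @param reference Reference ids (defaults to focal set).
#' @param t Equivalent-generation vector for the whole pedigree (optional;
#'   computed if missing).
#' @param max_exact Largest reference size for the all-pairs computation.
#' @param n_pairs Sample size beyond `max_exact`.
#' @param seed Seed for the pair sample.
#' @export
mean_rate_of_coancestry <- function(ped, reference = NULL, t = NULL,
                                    max_exact = 2000, n_pairs = 2e6,
                                    seed = 1L) {
  idx <- focal_indices(ped, reference)
  if (length(idx) < 2) stop("need at least two reference animals")
  if (is.null(t)) t <- generation_profiles(ped)$equivalent_generations
  F <- inbreeding(ped)
  m <- length(idx)
  if (m <= max_exact) {
    f <- coancestry(ped, ped$id[idx])
    tm <- outer(t[idx], t[idx], `+`) / 2
    dc <- 1 - (1 - f)^(1 / tm)
    mean(dc[upper.tri(dc)])
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    a <- sample(idx, n_pairs, replace = TRUE)
    b <- sample(idx, n_pairs, replace = TRUE)
    keep <- a != b
    a <- a[keep]; b <- b[keep]
    # coancestries for sampled pairs via products on the distinct columns
    cols <- unique(b)
    X <- matrix(0, nrow(ped), length(cols))
    X[cbind(cols, seq_along(cols))] <- 1
    A2 <- as.matrix(relationship_product(ped, X, F)) / 2
    f <- A2[cbind(a, match(b, cols))]
    mean(rate_of_coancestry(f, t[a], t[b]))
  }
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  invisible()
}

#' Degree of non-random mating
#'
#' alpha solves (1 - F) = (1 - C)(1 - alpha): positive when mates are more
#' related than random pairs (assortative), negative for avoidance of
#' related matings.
#'
#' @param F_bar Mean inbreeding.
#' @param C_bar Mean coancestry.
#' @export
nonrandom_mating <- function(F_bar, C_bar) {
  if (any(C_bar >= 1)) stop("mean coancestry must be < 1")
  1 - (1 - F_bar) / (1 - C_bar)
}

#' Genetic conservation index
#'
#' GCI_i = 1 / sum_k p_k^2 over the proportional contributions p_k of each
#' founder k to individual i, obtained by halving contributions up the
#' pedigree; pedigree slots with an unknown parent contribute to no founder.
#' An animal with no known ancestors is its own sole founder (GCI = 1).
#'
#' @param ped A `pedigree`.
#' @param ids Ids to evaluate (default: all records).
#' @return Named numeric vector of GCI values.
#' @export
genetic_conservation_index <- function(ped, ids = NULL) {
  idx <- if (is.null(ids)) seq_len(nrow(ped)) else focal_indices(ped, ids)
  si <- ped$sire_idx; di <- ped$dam_idx
  is_founder <- si == 0 & di == 0
  out <- numeric(length(idx))
  w <- numeric(nrow(ped))  # scratch weights
  for (k in seq_along(idx)) {
    i <- idx[k]
    if (is_founder[i]) { out[k] <- 1; next }
    w[i] <- 1
    founders_hit <- integer(0)
    # rows are topologically ordered: a single sweep from i down to 1 pushes
    # every animal's mass onto its parents; founders retain theirs
    for (j in i:1) {
      if (w[j] == 0) next
      if (is_founder[j]) { founders_hit <- c(founders_hit, j); next }
      s <- si[j]; d <- di[j]
      if (s > 0) w[s] <- w[s] + w[j] / 2
      if (d > 0) w[d] <- w[d] + w[j] / 2
      w[j] <- 0
    }
    p <- w[founders_hit]
    out[k] <- if (length(p)) 1 / sum(p^2) else 1
    w[founders_hit] <- 0
  }
  names(out) <- ped$id[idx]
  out
}

#' Population diversity summary
#'
#' Per-individual and population-level pedigree diversity statistics:
#' inbreeding F, average relatedness AR, individual rate of inbreeding dF,
#' genetic conservation index GCI, generation counts; population means of F
#' and coancestry (self-pairs included), mean rates of inbreeding and
#' coancestry, non-random mating degree alpha, the shares of inbred
#' (F > 0) and highly inbred (F > 0.10) animals, and the maximum F.
#' Population-level values describe the reference (focal) set; per-individual
#' columns cover the reference animals.
#'
#' @param ped A `pedigree`.
#' @param reference Reference ids (defaults to the focal set, else all).
#' @param highly_inbred_threshold F above which an animal counts as highly
#'   inbred.
#' @param ... Passed to [mean_rate_of_coancestry()].
#' @return A list of class `diversity_summary` with elements `individuals`
#'   (data frame) and `population` (named list).
#' @export
diversity_summary <- function(ped, reference = NULL,
                              highly_inbred_threshold = 0.10, ...) {
  idx <- focal_indices(ped, reference)
  F <- inbreeding(ped)
  AR <- average_relatedness(ped, F)
  gp <- generation_profiles(ped)
  t <- gp$equivalent_generations
  dF <- rate_of_inbreeding(F[idx], t[idx])
  gci <- genetic_conservation_index(ped, ped$id[idx])
  Cbar <- mean_coancestry(ped, ped$id[idx], F)
  dCbar <- mean_rate_of_coancestry(ped, ped$id[idx], t, ...)
  Fbar <- mean(F[idx])
  individuals <- data.frame(
    id = ped$id[idx], breed = ped$breed[idx],
    F = unname(F[idx]), AR = unname(AR[idx]), dF = unname(dF),
    GCI = unname(gci),
    max_generations = gp$max_generations[idx],
    complete_generations = gp$complete_generations[idx],
    equivalent_generations = t[idx],
    stringsAsFactors = FALSE)
  population <- list(
    n = length(idx),
    mean_F = Fbar,
    mean_coancestry = Cbar,
    mean_rate_inbreeding = mean(dF),
    mean_rate_coancestry = dCbar,
    alpha = nonrandom_mating(Fbar, Cbar),
    pct_inbred = 100 * mean(F[idx] > 0),
    pct_highly_inbred = 100 * mean(F[idx] > highly_inbred_threshold),
    max_F = max(F[idx]),
    mean_GCI = mean(gci))
  structure(list(individuals = individuals, population = population),
            class = "diversity_summary")
}
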