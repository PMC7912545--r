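# Mean genetic contribution of every animal to the reference set: the
# reference-weight vector pushed up the pedigree, halving at each step.
# Entry j is the expected fraction of the reference gene pool descending
# through j (its own contribution for reference members). `block` marks
# animals at which upward propagation stops (used for marginal
# contributions of selected ancestors).
reference_contribution <- function(ped, ref_idx, block = NULL) {
  n <- nrow(ped)
  si <- ped$sire_idx; di <- ped$dam_idx
  u <- numeric(n)
  u[ref_idx] <- 1 / length(ref_idx)
  blocked <- logical(n)
  if (!is.null(block)) blocked[block] <- TRUE
  for (i in n:1) {
    if (u[i] == 0 || blocked[i]) next
    s <- si[i]; d <- di[i]
    if (s > 0) u[s] <- u[s] + 0.5 * u[i]
    if (d > 0) u[d] <- u[d] + 0.5 * u[i]
  }
  u
}

# Origin-walk contributions for ancestor selection. The walk for a
# reference gene starts one meiosis up: mass goes to the known parents,
# while unknown-parent slots leave their share on the reference animal
# itself (it is its own base individual for the untraced part). `u` counts
# mass passing through each animal (blocked at `block`); `own` holds the
# terminated self-origin mass.
ancestor_contribution <- function(ped, ref_idx, block = integer(0)) {
  n <- nrow(ped)
  si <- ped$sire_idx; di <- ped$dam_idx
  u <- numeric(n)
  own <- numeric(n)
  blocked <- logical(n); blocked[block] <- TRUE
  m <- length(ref_idx)
  for (i in ref_idx) {
    if (blocked[i]) next
    s <- si[i]; d <- di[i]
    if (s > 0) u[s] <- u[s] + 0.5 / m else own[i] <- own[i] + 0.5 / m
    if (d > 0) u[d] <- u[d] + 0.5 / m else own[i] <- own[i] + 0.5 / m
  }
  for (i in n:1) {
    if (u[i] == 0 || blocked[i]) next
    s <- si[i]; d <- di[i]
    if (s > 0) u[s] <- u[s] + 0.5 * u[i]
    if (d > 0) u[d] <- u[d] + 0.5 * u[i]
  }
  list(u = u, own = own)
}

# Fraction of each animal's genome originating from the `from` set (itself
# counting fully): forward recursion down the pedigree.
genome_fraction_from <- function(ped, from) {
  n <- nrow(ped)
  si <- ped$sire_idx; di <- ped$dam_idx
  g <- numeric(n)
  in_from <- logical(n); in_from[from] <- TRUE
  for (i in seq_len(n)) {
    if (in_from[i]) { g[i] <- 1; next }
    s <- si[i]; d <- di[i]
    g[i] <- (if (s > 0) 0.5 * g[s] else 0) + (if (d > 0) 0.5 * g[d] else 0)
  }
  g
}

#' Founder accounting and probabilities of gene origin
#'
#' Counts founders (both parents unknown), the base population (at least one
#' unknown parent) and the "actual base" under the half-founder convention
#' (an animal with exactly one unknown parent counts 0.5), and computes each
#' founder's probability of gene origin q_k: its mean genetic contribution
#' to the reference set. The q_k sum to the mean known-pedigree fraction of
#' the reference (1 at full pedigree completeness).
#'
#' @param ped A `pedigree`.
#' @param reference Reference ids (defaults to focal set, else all records).
#' @return List of class `founder_accounting` with counts and a
#'   `founder_probabilities` data frame (id, q) sorted by decreasing q.
#' @export
founder_accounting <- function(ped, reference = NULL) {
  ref <- focal_indices(ped, reference)
  if (!length(ref)) stop("empty reference")
  unk <- (ped$sire_idx == 0) + (ped$dam_idx == 0)
  founders <- which(unk == 2L)
  u <- reference_contribution(ped, ref)
  q <- u[founders]
  ord <- order(q, decreasing = TRUE)
  structure(list(
    n_founders = length(founders),
    base_population = sum(unk >= 1L),
    actual_base = sum(unk == 2L) + 0.5 * sum(unk == 1L),
    founder_probabilities = data.frame(id = ped$id[founders][ord],
                                       q = q[ord],
                                       stringsAsFactors = FALSE)),
    class = "founder_accounting")
}

#' Effective number of founders
#'
#' fe = 1 / sum q_k^2 over founder probabilities of gene origin; equals the
#' founder count when all founders contribute equally and shrinks as
#' contributions become unbalanced.
#'
#' @param founder_probabilities Numeric vector of q_k (or the data frame
#'   from [founder_accounting()]).
#' @export
effective_founders <- function(founder_probabilities) {
  q <- if (is.data.frame(founder_probabilities)) founder_probabilities$q
       else founder_probabilities
  if (any(q < 0)) stop("founder probabilities must be >= 0")
  s <- sum(q^2)
  if (s == 0) stop("all founder probabilities are zero")
  1 / s
}

#' Effective number of ancestors and marginal contributions
#'
#' Iterative selection of major ancestors: at each round the ancestor
#' (founder or not) with the largest marginal contribution to the reference
#' gene pool is chosen, where "marginal" means the probability that a
#' reference gene descends through that ancestor without passing through
#' any previously selected one, and discounting the part of the candidate's
#' own genome already explained by the selected set. fa = 1 / sum p_k^2.
#' Ties are broken in lexicographic id order.
#'
#' @param ped A `pedigree`.
#' @param reference Reference ids (defaults to focal set, else all records).
#' @param tol Selection stops when the residual marginal contribution falls
#'   below `tol`.
#' @param max_ancestors Optional cap on the number of selected ancestors.
#' @return List of class `ancestor_report`: `fa`, `n_ancestors_selected`,
#'   `marginal_contributions` (data frame id, p, cumulative) and
#'   `explained` (sum of p).
#' @export
effective_ancestors <- function(ped, reference = NULL, tol = 1e-8,
                                max_ancestors = Inf) {
  ref <- focal_indices(ped, reference)
  if (!length(ref)) stop("empty reference")
  n <- nrow(ped)
  selected <- integer(0)
  p <- numeric(0)
  repeat {
    ac <- ancestor_contribution(ped, ref, block = selected)
    if (length(selected)) {
      g <- genome_fraction_from(ped, selected)
      marg <- ac$u * (1 - g) + ac$own
    } else marg <- ac$u + ac$own
    marg[selected] <- 0
    best <- max(marg)
    if (best < tol || length(selected) >= max_ancestors) break
    cand <- which(marg > best - 1e-15)
    pick <- cand[order(ped$id[cand])][1]
    selected <- c(selected, pick)
    p <- c(p, marg[pick])
    if (sum(p) > 1 - tol) break
    if (length(selected) == n) break
  }
  structure(list(
    fa = 1 / sum(p^2),
    n_ancestors_selected = length(selected),
    marginal_contributions = data.frame(id = ped$id[selected], p = p,
                                        cumulative = cumsum(p),
                                        stringsAsFactors = FALSE),
    explained = sum(p)),
    class = "ancestor_report")
}

#' Founder genome equivalents
#'
#' fg is the number of equally contributing founders with no random loss of
#' alleles that would yield the diversity observed in the reference:
#' analytically the reciprocal of twice the mean reference coancestry
#' (self-pairs included), or by gene dropping - Monte-Carlo transmission of
#' labelled founder alleles down the pedigree, with fg the reciprocal of
#' twice the mean simulated identity probability.
#'
#' @param ped A `pedigree`.
#' @param reference Reference ids (defaults to focal set, else all records).
#' @param method `"analytic"` or `"gene_drop"`.
#' @param n_reps Gene-dropping replicates (>= 100).
#' @param seed Seed for gene dropping.
#' @return For `"analytic"`, the fg value. For `"gene_drop"`, fg with
#'   attributes `se` (Monte-Carlo standard error of the mean identity) and
#'   `mean_identity`.
#' @export
founder_genome_equivalents <- function(ped, reference = NULL,
                                       method = c("analytic", "gene_drop"),
                                       n_reps = 10000, seed = 1L) {
  method <- match.arg(method)
  ref <- focal_indices(ped, reference)
  if (!length(ref)) stop("empty reference")
  if (method == "analytic")
    return(1 / (2 * mean_coancestry(ped, ped$id[ref])))
  if (n_reps < 100) stop("n_reps < 100 gives unstable gene-drop estimates")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- nrow(ped)
  si <- ped$sire_idx; di <- ped$dam_idx
  # two distinct allele labels per founder; each unknown-parent slot of a
  # non-founder is a distinct phantom source with its own unique label
  a1 <- matrix(0L, n, n_reps)
  a2 <- matrix(0L, n, n_reps)
  next_label <- 0L
  new_labels <- function(k) {
    labs <- next_label + seq_len(k)
    next_label <<- next_label + k
    labs
  }
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (s > 0) {
      pickA <- stats::runif(n_reps) < 0.5
      a1[i, ] <- ifelse(pickA, a1[s, ], a2[s, ])
    } else a1[i, ] <- new_labels(1)
    if (d > 0) {
      pickA <- stats::runif(n_reps) < 0.5
      a2[i, ] <- ifelse(pickA, a1[d, ], a2[d, ])
    } else a2[i, ] <- new_labels(1)
  }
  m <- length(ref)
  ident <- vapply(seq_len(n_reps), function(r) {
    counts <- table(c(a1[ref, r], a2[ref, r]))
    sum((counts / (2 * m))^2)
  }, numeric(1))
  fg <- 1 / (2 * mean(ident))
  attr(fg, "se") <- stats::sd(ident) / sqrt(n_reps)
  attr(fg, "mean_identity") <- mean(ident)
  fg
}

#' Genetic diversity retained and its loss components
#'
#' GD = 1 - 1/(2 fg) is the diversity retained accounting for all losses
#' since the founders; GD* = 1 - 1/(2 fe) accounts only for unequal founder
#' contributions. Their difference is the loss from drift accumulated since
#' foundation, and Nef = 1/(1/fg - 1/fe) is the effective number of
#' non-founders partitioning the loss between founder imbalance and later
#' bottlenecks.
#'
#' @param fe Effective number of founders.
#' @param fg Founder genome equivalents (fg <= fe).
#' @return List of class `diversity_losses`: `GD`, `GD_star`, `loss_total`
#'   (= 1 - GD), `loss_founder_imbalance` (= 1 - GD*), `loss_drift`
#'   (= GD* - GD) and `Nef` (`Inf`, flagged `no_nonfounder_bottleneck`,
#'   when fe = fg).
#' @export
diversity_losses <- function(fe, fg) {
  if (fg <= 0) stop("fg must be > 0")
  if (fe < fg) stop("fe < fg violates gene-origin theory; ",
                    "check upstream contributions")
  GD <- 1 - 1 / (2 * fg)
  GDs <- 1 - 1 / (2 * fe)
  Nef <- if (fe == fg) Inf else 1 / (1 / fg - 1 / fe)
  structure(list(GD = GD, GD_star = GDs, loss_total = 1 - GD,
                 loss_founder_imbalance = 1 - GDs, loss_drift = GDs - GD,
                 Nef = Nef,
                 no_nonfounder_bottleneck = !is.finite(Nef)),
            class = "diversity_losses")
}

#' Partition mean inbreeding over common ancestors
#'
#' Decomposes the mean inbreeding of the reference into additive
#' contributions of common ancestors (inbreeding loops): an animal's F is
#' the coancestry of its parents, which splits exactly over ancestors j as
#' 0.5 T[s,j] D_j T[d,j] with T the gene-flow matrix and D the Mendelian
#' sampling variances. Contributions sum to the reference mean F.
#'
#' @param ped A `pedigree` (dense gene-flow rows are built; intended for
#'   pedigrees up to a few thousand records).
#' @param reference Reference ids (defaults to focal set, else all records).
#' @return List of class `inbreeding_partition`: `contributions` (data
#'   frame id, contribution, sorted decreasing; zero rows dropped) and
#'   `mean_F`.
#' @export
partition_inbreeding <- function(ped, reference = NULL) {
  ref <- focal_indices(ped, reference)
  if (!length(ref)) stop("empty reference")
  n <- nrow(ped)
  if (n > 5000)
    stop("inbreeding partition builds dense gene-flow rows; pedigree too ",
         "large (", n, " records)")
  si <- ped$sire_idx; di <- ped$dam_idx
  F <- inbreeding(ped)
  D <- mendelian_variance(ped, F)
  T <- diag(n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (s > 0) T[i, ] <- T[i, ] + 0.5 * T[s, ]
    if (d > 0) T[i, ] <- T[i, ] + 0.5 * T[d, ]
  }
  contrib <- numeric(n)
  for (i in ref) {
    s <- si[i]; d <- di[i]
    if (s == 0 || d == 0) next
    contrib <- contrib + 0.5 * D * T[s, ] * T[d, ] / length(ref)
  }
  keep <- which(contrib > 0)
  ord <- keep[order(contrib[keep], decreasing = TRUE)]
  structure(list(
    contributions = data.frame(id = ped$id[ord],
                               contribution = contrib[ord],
                               stringsAsFactors = FALSE),
    mean_F = mean(F[ref])),
    class = "inbreeding_partition")
}

#' Gene-origin report
#'
#' Bundles founder accounting, effective numbers (fe, fa, fg), diversity
#' losses and marginal ancestor contributions for a reference population.
#'
#' @param ped A `pedigree`.
#' @param reference Reference ids (defaults to the focal set - typically the
#'   living animals after [subset_population()] - else all records).
#' @param tol Passed to [effective_ancestors()].
#' @return List of class `gene_origin_report`.
#' @export
gene_origin_report <- function(ped, reference = NULL, tol = 1e-8) {
  fa_acc <- founder_accounting(ped, reference)
  fe <- effective_founders(fa_acc$founder_probabilities)
  anc <- effective_ancestors(ped, reference, tol = tol)
  fg <- founder_genome_equivalents(ped, reference, method = "analytic")
  losses <- diversity_losses(fe, fg)
  structure(c(fa_acc[c("n_founders", "base_population", "actual_base")],
              list(fe = fe, fa = anc$fa, fg = fg,
                   n_ancestors_selected = anc$n_ancestors_selected,
                   GD = losses$GD, GD_star = losses$GD_star,
                   Nef = losses$Nef,
                   founder_probabilities = fa_acc$founder_probabilities,
                   marginal_contributions = anc$marginal_contributions)),
            class = "gene_origin_report")
}
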