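# Independent oracles and fixture builders. These deliberately use the
# naive O(n^2) textbook constructions, never the package's indirect
# algorithms, so agreement is a genuine cross-check.

# quick pedigree from parallel vectors
mk_ped <- function(id, sire = NA, dam = NA, sex = NULL, birth = NULL,
                   breed = NULL, alive = NULL) {
  df <- data.frame(id = id, sire = sire, dam = dam,
                   stringsAsFactors = FALSE)
  if (!is.null(sex)) df$sex <- sex
  if (!is.null(birth)) df$birth_date <- birth
  if (!is.null(breed)) df$breed <- breed
  if (!is.null(alive)) df$alive <- alive
  as_pedigree(df)
}

# dense additive relationship matrix by the recursive tabular method
tabular_A <- function(ped) {
  n <- nrow(ped)
  s <- ped$sire_idx; d <- ped$dam_idx
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    if (i > 1) {
      j <- seq_len(i - 1)
      aj <- numeric(i - 1)
      if (s[i] > 0) aj <- aj + 0.5 * A[j, s[i]]
      if (d[i] > 0) aj <- aj + 0.5 * A[j, d[i]]
      A[j, i] <- A[i, j] <- aj
    }
    A[i, i] <- 1 + (if (s[i] > 0 && d[i] > 0) 0.5 * A[s[i], d[i]] else 0)
  }
  A
}

# P(a random gene of a random `ref` animal originates through `j` while
# never passing through any id in `avoid`), by direct recursion on the
# gene-origin walk. The walk starts one meiosis up (mass to the known
# parents); an unknown-parent slot ends the walk on the animal itself,
# which is its own base individual for the untraced share. Oracle for
# marginal ancestor contributions.
walk_prob <- function(ped, ref, j, avoid = character(0)) {
  s <- stats::setNames(ped$sire, ped$id)
  d <- stats::setNames(ped$dam, ped$id)
  avoids <- function(i) {  # P(walk from i upward avoids `avoid`)
    if (i %in% avoid) return(0)
    up <- function(p) if (is.na(p)) 1 else avoids(p)
    0.5 * up(s[[i]]) + 0.5 * up(d[[i]])
  }
  visit <- function(i) {   # walk currently AT i (counts as passing i)
    if (i %in% avoid) return(0)
    if (i == j) return(avoids(i))
    up <- function(p) if (is.na(p)) 0 else visit(p)
    0.5 * up(s[[i]]) + 0.5 * up(d[[i]])
  }
  start <- function(i) {   # ref animal: gene attributed one meiosis up
    if (i %in% avoid) return(0)
    self <- if (i == j) (is.na(s[[i]]) + is.na(d[[i]])) / 2 else 0
    up <- function(p) if (is.na(p)) 0 else visit(p)
    self + 0.5 * up(s[[i]]) + 0.5 * up(d[[i]])
  }
  mean(vapply(ref, start, numeric(1)))
}

# greedy major-ancestor selection computed entirely through the walk oracle
oracle_ancestors <- function(ped, ref, tol = 1e-8) {
  sel <- character(0); p <- numeric(0)
  repeat {
    cand <- setdiff(ped$id, sel)
    marg <- vapply(cand, function(j) walk_prob(ped, ref, j, sel), numeric(1))
    if (max(marg) < tol) break
    best <- cand[order(-marg, cand)][1]
    sel <- c(sel, best); p <- c(p, max(marg))
    if (sum(p) > 1 - tol) break
  }
  list(ids = sel, p = p)
}

# random valid pedigree with overlapping unknown parents, for property tests
random_ped <- function(n = 200, n_founders = 30, missing = 0.1, seed = 1) {
  set.seed(seed)
  id <- sprintf("R%03d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  sex <- c(rep(c("male", "female"), length.out = n_founders),
           sample(c("male", "female"), n - n_founders, replace = TRUE))
  for (i in (n_founders + 1):n) {
    males <- which(sex[seq_len(i - 1)] == "male")
    females <- which(sex[seq_len(i - 1)] == "female")
    if (runif(1) > missing && length(males))
      sire[i] <- id[sample(males, 1)]
    if (runif(1) > missing && length(females))
      dam[i] <- id[sample(females, 1)]
  }
  mk_ped(id, sire, dam, sex = sex)
}

# ultrametric distance matrix from a random coalescent-style tree
random_ultrametric <- function(k = 6, seed = 1) {
  set.seed(seed)
  labs <- LETTERS[seq_len(k)]
  height <- stats::setNames(rep(0, k), labs)
  members <- lapply(labs, identity); names(members) <- labs
  D <- matrix(0, k, k, dimnames = list(labs, labs))
  h <- 0
  while (length(members) > 1) {
    h <- h + stats::runif(1, 0.5, 2)
    pick <- sample(names(members), 2)
    for (a in members[[pick[1]]]) for (b in members[[pick[2]]])
      D[a, b] <- D[b, a] <- 2 * h
    members[[pick[1]]] <- c(members[[pick[1]]], members[[pick[2]]])
    members[[pick[2]]] <- NULL
  }
  D
}

# gaussian three-group data for CDA tests
sim_groups <- function(n_per = c(60, 50, 40), shift = 2, p = 4, seed = 1) {
  set.seed(seed)
  mus <- rbind(rep(0, p),
               c(shift, rep(0, p - 1)),
               c(0, shift, rep(0, p - 2)))
  X <- do.call(rbind, lapply(1:3, function(g)
    matrix(stats::rnorm(n_per[g] * p, mean = rep(mus[g, ], each = n_per[g])),
           n_per[g], p)))
  colnames(X) <- paste0("v", seq_len(p))
  list(X = X, groups = rep(c("G1", "G2", "G3"), n_per))
}
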