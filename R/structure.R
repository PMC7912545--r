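#' Realized effective population size from a mean rate
#'
#' Ne = 1 / (2 * rate), applicable to mean rates of inbreeding (giving NeF)
#' or of coancestry (giving NeC).
#'
#' @param mean_rate Mean per-generation rate of inbreeding or coancestry.
#' @export
effective_size <- function(mean_rate) {
  if (any(mean_rate <= 0))
    stop("rate <= 0: population not losing diversity; ",
         "effective size undefined")
  1 / (2 * mean_rate)
}

#' Number of equivalent subpopulations
#'
#' S = NeC / NeF; values above 1 signal substructure, below 1 signal
#' admixture/mixing.
#'
#' @param NeC Effective size via mean rate of coancestry.
#' @param NeF Effective size via mean rate of inbreeding.
#' @export
equivalent_subpopulations <- function(NeC, NeF) {
  stopifnot(NeC > 0, NeF > 0)
  NeC / NeF
}

# group labels resolved against a pedigree: named vector id -> label,
# defaulting to the breed column over the focal set
resolve_labels <- function(ped, labels = NULL) {
  if (is.null(labels)) {
    idx <- focal_indices(ped, NULL)
    labels <- stats::setNames(ped$breed[idx], ped$id[idx])
    labels <- labels[!is.na(labels)]
  }
  if (is.null(names(labels))) stop("labels must be named by animal id")
  split(names(labels), as.character(labels))
}

# matrix of mean coancestries between (and within) groups, plus sizes and
# mean inbreeding; one indirect A-product per group
group_coancestries <- function(ped, groups) {
  g <- length(groups)
  F <- inbreeding(ped)
  n <- nrow(ped)
  X <- matrix(0, n, g)
  sizes <- integer(g)
  for (k in seq_len(g)) {
    idx <- focal_indices(ped, groups[[k]])
    sizes[k] <- length(idx)
    X[idx, k] <- 1 / length(idx)
  }
  AX <- as.matrix(relationship_product(ped, X, F))
  fbar <- crossprod(X, AX) / 2
  fbar <- (fbar + t(fbar)) / 2
  dimnames(fbar) <- list(names(groups), names(groups))
  meanF <- vapply(seq_len(g), function(k)
    mean(F[focal_indices(ped, groups[[k]])]), numeric(1))
  list(f = fbar, sizes = sizes, mean_F = meanF)
}

#' Wright's fixation indices from pedigree coancestries
#'
#' Computes FIS, FST and FIT from mean self-inbreeding, mean
#' within-subpopulation coancestry and metapopulation mean coancestry
#' (subpopulations weighted by census size):
#' FIS = (F - fw)/(1 - fw), FST = (fw - fT)/(1 - fT),
#' FIT = (F - fT)/(1 - fT), so that (1 - FIT) = (1 - FIS)(1 - FST)
#' identically.
#'
#' @param ped A `pedigree`.
#' @param labels Named character vector id -> subpopulation label; defaults
#'   to the breed column over the focal set.
#' @return List of class `f_statistics`: `FIS`, `FST`, `FIT`, plus the
#'   underlying `mean_F`, `mean_f_within`, `mean_f_total` and group sizes.
#' @export
wright_f_statistics <- function(ped, labels = NULL) {
  groups <- resolve_labels(ped, labels)
  if (length(groups) < 2) stop("need at least two subpopulations")
  gc <- group_coancestries(ped, groups)
  w <- gc$sizes / sum(gc$sizes)
  Fbar <- sum(w * gc$mean_F)
  fw <- sum(w * diag(gc$f))
  fT <- drop(t(w) %*% gc$f %*% w)
  structure(list(FIS = (Fbar - fw) / (1 - fw),
                 FST = (fw - fT) / (1 - fT),
                 FIT = (Fbar - fT) / (1 - fT),
                 mean_F = Fbar, mean_f_within = fw, mean_f_total = fT,
                 sizes = stats::setNames(gc$sizes, names(groups))),
            class = "f_statistics")
}

#' Nei minimum distances between subpopulations
#'
#' The kinship analogue of Nei's minimum genetic distance on pedigree
#' coancestries: D_ij = (f_ii + f_jj)/2 - f_ij, where f are mean
#' coancestries within and between subpopulations. Symmetric with a zero
#' diagonal.
#'
#' @inheritParams wright_f_statistics
#' @return Symmetric distance matrix over subpopulation labels.
#' @export
nei_minimum_distance <- function(ped, labels = NULL) {
  groups <- resolve_labels(ped, labels)
  if (length(groups) < 2) stop("need at least two subpopulations")
  f <- group_coancestries(ped, groups)$f
  D <- (outer(diag(f), diag(f), `+`)) / 2 - f
  D[abs(D) < 1e-15] <- 0
  diag(D) <- 0
  D
}

#' UPGMA tree from a distance matrix
#'
#' Standard unweighted pair-group agglomeration with arithmetic-average
#' linkage; the result is ultrametric, with each pair of leaves at height
#' half their cophenetic distance. Agglomeration is delegated to
#' [stats::hclust()] (`method = "average"`) and the tree returned as an
#' [ape::as.phylo()] object.
#'
#' @param distance_matrix Symmetric non-negative matrix with zero diagonal.
#' @return An `ape` `phylo` tree (rooted, ultrametric).
#' @export
upgma_tree <- function(distance_matrix) {
  D <- as.matrix(distance_matrix)
  if (!isSymmetric(unname(D), tol = 1e-12))
    stop("distance matrix must be symmetric")
  if (any(diag(D) != 0)) stop("distance matrix must have a zero diagonal")
  if (any(D < 0)) stop("distances must be non-negative")
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  ape::as.phylo(hc)
}

#' Write a tree in Newick format
#'
#' @param tree A `phylo` tree.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Population-structure report
#'
#' Realized effective sizes from the mean rates of inbreeding (NeF) and
#' coancestry (NeC) of the reference set, the number of equivalent
#' subpopulations S = NeC/NeF, Wright's fixation indices, the Nei minimum
#' distance matrix over subpopulations, and its UPGMA tree in Newick form.
#'
#' @param ped A `pedigree`.
#' @param labels Named id -> subpopulation vector (default: breed column
#'   over the focal set).
#' @param reference Reference ids for the rate computations (defaults to
#'   the focal set).
#' @param ... Passed to [mean_rate_of_coancestry()].
#' @return List of class `structure_report`.
#' @export
structure_report <- function(ped, labels = NULL, reference = NULL, ...) {
  idx <- focal_indices(ped, reference)
  gp <- generation_profiles(ped)
  F <- inbreeding(ped)
  dF <- mean(rate_of_inbreeding(F[idx], gp$equivalent_generations[idx]))
  dC <- mean_rate_of_coancestry(ped, ped$id[idx],
                                gp$equivalent_generations, ...)
  NeF <- effective_size(dF)
  NeC <- effective_size(dC)
  fst <- wright_f_statistics(ped, labels)
  D <- nei_minimum_distance(ped, labels)
  tree <- upgma_tree(D)
  structure(list(NeF = NeF, NeC = NeC,
                 S = equivalent_subpopulations(NeC, NeF),
                 mean_rate_inbreeding = dF, mean_rate_coancestry = dC,
                 FIS = fst$FIS, FST = fst$FST, FIT = fst$FIT,
                 nei_matrix = D, newick = ape::write.tree(tree)),
            class = "structure_report")
}
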