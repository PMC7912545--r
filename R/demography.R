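#' Generation numbers for every animal
#'
#' Three pedigree-depth measures per record: the maximum number of traced
#' generations (longest chain of known parents), the number of complete
#' generations (deepest generation at which all 2^g ancestor slots are
#' known), and the number of equivalent generations
#' t = sum over known ancestors of (1/2)^g. All three are 0 for founders and
#' satisfy complete <= equivalent <= max.
#'
#' @param ped A `pedigree`.
#' @return Data frame with columns `id`, `max_generations`,
#'   `complete_generations`, `equivalent_generations`, in pedigree order.
#' @export
generation_profiles <- function(ped) {
  n <- nrow(ped)
  si <- ped$sire_idx; di <- ped$dam_idx
  maxg <- integer(n); comg <- integer(n); eqg <- numeric(n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    ms <- if (s > 0) maxg[s] + 1L else 0L
    md <- if (d > 0) maxg[d] + 1L else 0L
    maxg[i] <- max(ms, md)
    comg[i] <- if (s > 0 && d > 0) 1L + min(comg[s], comg[d]) else 0L
    eqg[i] <- (if (s > 0) 0.5 * (1 + eqg[s]) else 0) +
              (if (d > 0) 0.5 * (1 + eqg[d]) else 0)
  }
  data.frame(id = ped$id, max_generations = maxg,
             complete_generations = comg, equivalent_generations = eqg,
             stringsAsFactors = FALSE)
}

#' Generation profile of a single animal
#'
#' @param ped A `pedigree`.
#' @param id Animal id.
#' @return One-row data frame as in [generation_profiles()].
#' @export
generation_profile <- function(ped, id) {
  idx <- focal_indices(ped, id)
  generation_profiles(ped)[idx, , drop = FALSE]
}

#' Pedigree completeness profile
#'
#' For each ascending generation k = 1..`depth`, the mean over the reference
#' animals of (known ancestors at generation k) / 2^k, counting duplicated
#' ancestors once per pedigree slot. The aggregate pedigree completeness
#' index (PCI) is the simple mean of the per-generation proportions over
#' generations 1..min(depth, 5).
#'
#' @param ped A `pedigree`.
#' @param reference Reference ids (defaults to focal set, else all records).
#' @param depth Number of ascending generations to profile.
#' @return List of class `completeness_profile` with `per_generation`
#'   (numeric vector of proportions) and `pci`.
#' @export
completeness <- function(ped, reference = NULL, depth = 5) {
  if (depth < 1) stop("depth must be >= 1")
  idx <- focal_indices(ped, reference)
  if (!length(idx)) stop("empty reference")
  n <- nrow(ped)
  si <- ped$sire_idx; di <- ped$dam_idx
  # known[i, k]: number of known ancestor slots of i at generation k
  known <- matrix(0, n, depth)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    known[i, 1] <- (s > 0) + (d > 0)
    if (depth > 1) {
      for (k in 2:depth) {
        known[i, k] <- (if (s > 0) known[s, k - 1] else 0) +
                       (if (d > 0) known[d, k - 1] else 0)
      }
    }
  }
  prop <- colMeans(known[idx, , drop = FALSE]) / 2^(seq_len(depth))
  names(prop) <- paste0("g", seq_len(depth))
  structure(list(per_generation = prop,
                 pci = mean(prop[seq_len(min(depth, 5))])),
            class = "completeness_profile")
}

#' Generation intervals, parental ages and progeny statistics
#'
#' Splits every dated parent-offspring link into the four gametic pathways
#' (sire-son, sire-daughter, dam-son, dam-daughter). The generation interval
#' of a pathway is the mean age of the parent at the birth of the offspring
#' that themselves left registered progeny; the mean parental age uses all
#' offspring. Also reports progeny counts per sire and per dam, the share of
#' breeding animals (at least one registered offspring) by sex, and the
#' sex ratio.
#'
#' @param ped A `pedigree` with birth dates.
#' @return List of class `interval_report` with `pathways` (data frame:
#'   pathway, interval mean/sd/n, parental-age mean/sd/n), `progeny`
#'   (per-sire and per-dam summaries) and `undated_links` (count skipped).
#' @export
generation_intervals <- function(ped) {
  n <- nrow(ped)
  has_prog <- logical(n)
  has_prog[ped$sire_idx[ped$sire_idx > 0]] <- TRUE
  has_prog[ped$dam_idx[ped$dam_idx > 0]] <- TRUE

  links <- rbind(
    data.frame(parent = ped$sire_idx, off = seq_len(n), role = "sire"),
    data.frame(parent = ped$dam_idx, off = seq_len(n), role = "dam"))
  links <- links[links$parent > 0, ]
  age <- ped$birth[links$off] - ped$birth[links$parent]
  undated <- sum(is.na(age))
  ok <- !is.na(age)
  links <- links[ok, ]; age <- age[ok]
  if (any(age <= 0)) warning(sum(age <= 0),
    " link(s) with non-positive parental age retained; check birth dates")
  off_sex <- ped$sex[links$off]
  off_sex[off_sex == "unknown"] <- NA
  pathway <- paste0(links$role, "-",
                    ifelse(off_sex == "male", "son", "daughter"))
  reproductive <- has_prog[links$off]

  paths <- c("sire-son", "sire-daughter", "dam-son", "dam-daughter")
  rows <- lapply(paths, function(p) {
    sel <- which(!is.na(off_sex) & pathway == p)
    gi <- age[sel][reproductive[sel]]
    data.frame(pathway = p,
               interval_mean = if (length(gi)) mean(gi) else NA_real_,
               interval_sd = if (length(gi) > 1) stats::sd(gi) else NA_real_,
               interval_n = length(gi),
               parental_age_mean = if (length(sel)) mean(age[sel]) else NA_real_,
               parental_age_sd = if (length(sel) > 1) stats::sd(age[sel]) else NA_real_,
               parental_age_n = length(sel), stringsAsFactors = FALSE)
  })
  pathways <- do.call(rbind, rows)
  if (all(pathways$parental_age_n == 0))
    stop("no dated parent-offspring link in any pathway")

  prog_sire <- table(ped$sire_idx[ped$sire_idx > 0])
  prog_dam <- table(ped$dam_idx[ped$dam_idx > 0])
  n_male <- sum(ped$sex == "male"); n_female <- sum(ped$sex == "female")
  progeny <- list(
    mean_per_sire = if (length(prog_sire)) mean(prog_sire) else NA_real_,
    max_per_sire = if (length(prog_sire)) max(prog_sire) else NA_real_,
    mean_per_dam = if (length(prog_dam)) mean(prog_dam) else NA_real_,
    max_per_dam = if (length(prog_dam)) max(prog_dam) else NA_real_,
    pct_males_breeding = if (n_male) 100 * sum(has_prog & ped$sex == "male") / n_male else NA_real_,
    pct_females_breeding = if (n_female) 100 * sum(has_prog & ped$sex == "female") / n_female else NA_real_,
    sex_ratio_m_f = if (n_female) n_male / n_female else NA_real_)
  structure(list(pathways = pathways, progeny = progeny,
                 undated_links = undated),
            class = "interval_report")
}
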