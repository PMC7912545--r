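#' Simulation configuration for synthetic pedigrees
#'
#' Bundles the parameters of the purebred generator. Defaults describe a
#' mid-sized closed horse studbook: a few dozen founders, constant census,
#' right-skewed sire usage (a dominant stallion covering a large share of
#' the matings), near-even sex ratio, a small share of unrecorded parents,
#' and an 8-year generation gap with birth-year jitter so generations
#' overlap.
#'
#' @param n_founders_per_breed Founders in generation 0 (>= 2).
#' @param n_generations Number of generations bred after the founders.
#' @param n_per_generation Offspring per generation (default: founder count).
#' @param progeny_distribution `list(type = "poisson")` for uniform sire
#'   sampling (progeny counts approximately Poisson), or
#'   `list(type = "skewed", max_sire_share = s)` where one dominant sire
#'   receives share `s` of all matings and the remainder is spread evenly.
#'   An optional `mean` element overrides `n_per_generation` as
#'   `round(mean * available sires)`.
#' @param sex_ratio Fraction of offspring that are male.
#' @param missing_parent_rate Probability that a parent slot of a
#'   non-founder is left unrecorded.
#' @param mortality_rate Probability a non-terminal-generation animal is
#'   flagged dead (terminal generation is always alive).
#' @param base_year First birth year.
#' @param generation_gap Years between successive generations.
#' @param seed Integer seed; a fixed seed makes the output byte-identical.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_founders_per_breed = 40, n_generations = 6,
                       n_per_generation = NULL,
                       progeny_distribution = list(type = "skewed",
                                                   max_sire_share = 0.25),
                       sex_ratio = 0.5, missing_parent_rate = 0.02,
                       mortality_rate = 0.35, base_year = 1960,
                       generation_gap = 8, seed = 1L) {
  stopifnot(n_founders_per_breed >= 2, n_generations >= 1,
            sex_ratio > 0, sex_ratio < 1,
            missing_parent_rate >= 0, missing_parent_rate <= 1,
            mortality_rate >= 0, mortality_rate <= 1)
  if (is.null(n_per_generation)) n_per_generation <- n_founders_per_breed
  structure(list(n_founders_per_breed = n_founders_per_breed,
                 n_generations = n_generations,
                 n_per_generation = n_per_generation,
                 progeny_distribution = progeny_distribution,
                 sex_ratio = sex_ratio,
                 missing_parent_rate = missing_parent_rate,
                 mortality_rate = mortality_rate,
                 base_year = base_year, generation_gap = generation_gap,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# sex vector with both sexes guaranteed present
draw_sexes <- function(n, p_male) {
  if (n < 2) stop("need at least 2 animals per generation")
  sx <- ifelse(stats::runif(n) < p_male, "male", "female")
  if (!any(sx == "male")) sx[sample.int(n, 1)] <- "male"
  if (!any(sx == "female")) sx[sample.int(n, 1)] <- "female"
  sx
}

sire_weights <- function(males, dist) {
  m <- length(males)
  if (identical(dist$type, "skewed") && m > 1) {
    s <- dist$max_sire_share
    w <- rep((1 - s) / (m - 1), m)
    w[1] <- s
    w
  } else rep(1 / m, m)
}

# internal: one purebred breed as a plain data frame (not yet validated)
sim_breed_frame <- function(cfg, breed) {
  gens <- vector("list", cfg$n_generations + 1)
  nf <- cfg$n_founders_per_breed
  jit <- stats::runif(nf, -1, 1)
  gens[[1]] <- data.frame(
    id = paste0(breed, "_0_", seq_len(nf)),
    sire = NA_character_, dam = NA_character_,
    sex = draw_sexes(nf, cfg$sex_ratio),
    birth_date = as.character(cfg$base_year + round(jit)),
    breed = breed, alive = TRUE, generation = 0L,
    stringsAsFactors = FALSE)
  for (g in seq_len(cfg$n_generations)) {
    prev <- gens[[g]]
    males <- prev$id[prev$sex == "male"]
    females <- prev$id[prev$sex == "female"]
    if (!length(males) || !length(females))
      stop("generation ", g - 1, " of breed ", breed,
           " has no available male or female")
    n <- cfg$n_per_generation
    if (!is.null(cfg$progeny_distribution$mean))
      n <- max(2L, round(cfg$progeny_distribution$mean * length(males)))
    sires <- sample(males, n, replace = TRUE,
                    prob = sire_weights(males, cfg$progeny_distribution))
    dams <- sample(females, n, replace = TRUE)
    drop_s <- stats::runif(n) < cfg$missing_parent_rate
    drop_d <- stats::runif(n) < cfg$missing_parent_rate
    yr <- cfg$base_year + g * cfg$generation_gap +
      round(stats::runif(n, -1, 1))
    gens[[g + 1]] <- data.frame(
      id = paste0(breed, "_", g, "_", seq_len(n)),
      sire = ifelse(drop_s, NA_character_, sires),
      dam = ifelse(drop_d, NA_character_, dams),
      sex = draw_sexes(n, cfg$sex_ratio),
      birth_date = as.character(yr),
      breed = breed, alive = TRUE, generation = g,
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, gens)
  nonterm <- df$generation < cfg$n_generations
  df$alive[nonterm] <- stats::runif(sum(nonterm)) >= cfg$mortality_rate
  df
}

finish_sim_ped <- function(df, fractions = NULL) {
  ped <- as_pedigree(df[c("id", "sire", "dam", "sex", "birth_date",
                          "breed", "alive")])
  ped$generation <- df$generation[match(ped$id, df$id)]
  if (!is.null(fractions))
    ped$blood_fraction <- unname(fractions[ped$id])
  ped
}

#' Simulate a closed purebred population
#'
#' Generation 0 consists of founders with both parents unknown; each later
#' generation draws sires from the previous generation's males according to
#' the configured progeny distribution and dams uniformly from its females.
#' Birth years advance by the generation gap with a +/- 1 year jitter.
#'
#' @param cfg A [sim_config()].
#' @param breed Breed label.
#' @return A validated `pedigree` with an extra `generation` column.
#' @export
simulate_purebred <- function(cfg, breed = "A") {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  finish_sim_ped(sim_breed_frame(cfg, breed))
}

#' Crossing scheme stages for a composite breed
#'
#' Helper constructing one stage of a composite-breed crossing scheme.
#'
#' @param sire_breed,dam_breed Breed labels of the parental pools (either a
#'   purebred label or the composite label).
#' @param sire_fraction,dam_fraction Blood fraction (share of ancestry from
#'   the first purebred) identifying the pool; 1 for purebred A, 0 for
#'   purebred B.
#' @param n Number of offspring the stage produces.
#' @export
cross_stage <- function(sire_breed, sire_fraction, dam_breed, dam_fraction,
                        n) {
  list(sire_breed = sire_breed, sire_fraction = sire_fraction,
       dam_breed = dam_breed, dam_fraction = dam_fraction, n = as.integer(n))
}

#' Default composite-breed crossing scheme
#'
#' A five-stage approximation of a staged two-breed composite programme:
#' first crosses of the two purebreds (blood fraction 1/2), backcrosses to
#' each purebred (3/4 and 1/4), a 3/4 x 1/4 cross fixing the 50:50
#' genotype, and a final intra-composite 1/2 x 1/2 stage.
#'
#' @param n Offspring per stage (recycled over the 5 stages).
#' @param breed_a,breed_b Purebred labels.
#' @param composite Composite breed label.
#' @export
composite_scheme_5050 <- function(n = 30, breed_a = "A", breed_b = "B",
                                  composite = "COMP") {
  n <- rep_len(n, 5)
  list(cross_stage(breed_a, 1, breed_b, 0, n[1]),
       cross_stage(breed_a, 1, composite, 0.5, n[2]),
       cross_stage(breed_b, 0, composite, 0.5, n[3]),
       cross_stage(composite, 0.75, composite, 0.25, n[4]),
       cross_stage(composite, 0.5, composite, 0.5, n[5]))
}

#' Crossing scheme yielding a composite with ~70:30 ancestry
#'
#' First crosses followed by repeated backcrossing to breed A and a final
#' cohort mixing 3/4- and 1/2-blood parents, so the terminal composite
#' cohort carries 0.625-0.75 (mean ~0.7) of its genome from breed A.
#'
#' @inheritParams composite_scheme_5050
#' @export
composite_scheme_7030 <- function(n = c(16, 68, 16), breed_a = "A",
                                  breed_b = "B", composite = "COMP") {
  n <- rep_len(n, 3)
  list(cross_stage(breed_a, 1, breed_b, 0, n[1]),
       cross_stage(breed_a, 1, composite, 0.5, n[2]),
       cross_stage(composite, 0.75, composite, 0.5, n[3]))
}

#' Simulate a two-breed composite population
#'
#' Simulates two closed purebred populations and then applies an ordered
#' crossing scheme. Every composite animal carries a `blood_fraction`
#' annotation equal to the mean of its parents' fractions (purebred A = 1,
#' purebred B = 0); the annotation is a simulator truth label only and is
#' never read by the analysis functions.
#'
#' @param cfgA,cfgB [sim_config()]s for the two purebreds.
#' @param scheme List of [cross_stage()]s; stages may reference fractions
#'   produced by earlier stages only.
#' @param seed Seed for the crossing draws.
#' @param breed_a,breed_b,composite Breed labels.
#' @return A merged `pedigree` containing both purebreds and the composite,
#'   with `generation` and `blood_fraction` columns.
#' @export
simulate_composite <- function(cfgA, cfgB,
                               scheme = composite_scheme_5050(),
                               seed = 1L, breed_a = "A", breed_b = "B",
                               composite = "COMP") {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfgA$seed)
  dfA <- sim_breed_frame(cfgA, breed_a)
  set.seed(cfgB$seed)
  dfB <- sim_breed_frame(cfgB, breed_b)
  set.seed(seed)
  df <- rbind(dfA, dfB)
  frac <- stats::setNames(ifelse(df$breed == breed_a, 1, 0), df$id)
  last_year <- max(as.numeric(df$birth_date))
  gap <- max(cfgA$generation_gap, cfgB$generation_gap)
  stage_no <- 0L
  for (st in scheme) {
    stage_no <- stage_no + 1L
    pool <- function(brd, fr, sx) {
      sel <- df$breed == brd & df$sex == sx &
        abs(frac[df$id] - fr) < 1e-9
      if (brd %in% c(breed_a, breed_b)) {
        # use the most recent purebred generation as the crossing pool
        gmax <- max(df$generation[df$breed == brd])
        sel <- sel & df$generation == gmax
      }
      df$id[sel]
    }
    sires <- pool(st$sire_breed, st$sire_fraction, "male")
    dams <- pool(st$dam_breed, st$dam_fraction, "female")
    if (!length(sires) || !length(dams))
      stop("stage ", stage_no, ": no ", if (!length(sires)) "sire" else "dam",
           " with breed ", if (!length(sires)) st$sire_breed else st$dam_breed,
           " and blood fraction ",
           if (!length(sires)) st$sire_fraction else st$dam_fraction,
           " is producible from earlier stages")
    n <- st$n
    s_draw <- sample(sires, n, replace = TRUE)
    d_draw <- sample(dams, n, replace = TRUE)
    yr <- last_year + stage_no * gap + round(stats::runif(n, -1, 1))
    off <- data.frame(
      id = paste0(composite, "_s", stage_no, "_", seq_len(n)),
      sire = s_draw, dam = d_draw,
      sex = draw_sexes(n, cfgA$sex_ratio),
      birth_date = as.character(yr),
      breed = composite, alive = TRUE,
      generation = max(df$generation) + 1L,
      stringsAsFactors = FALSE)
    frac[off$id] <- (frac[s_draw] + frac[d_draw]) / 2
    df <- rbind(df, off)
  }
  finish_sim_ped(df, fractions = frac)
}

#' Idealized random-mating population
#'
#' Discrete non-overlapping generations of constant size `n` with an equal
#' sex ratio and parents drawn uniformly at random (monogamy not enforced):
#' the Wright-Fisher-like idealization under which the realized effective
#' size recovered from rates of inbreeding is approximately `n`.
#'
#' @param n Even census size per generation.
#' @param generations Number of bred generations.
#' @param seed Integer seed.
#' @return A `pedigree` with a `generation` column; every animal alive.
#' @export
ideal_population <- function(n, generations, seed = 1L) {
  stopifnot(n %% 2 == 0, n >= 4, generations >= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sexes <- rep(c("male", "female"), each = n / 2)
  gens <- vector("list", generations + 1)
  gens[[1]] <- data.frame(id = paste0("I_0_", seq_len(n)),
                          sire = NA_character_, dam = NA_character_,
                          sex = sexes, birth_date = as.character(2000),
                          breed = "IDEAL", alive = TRUE, generation = 0L,
                          stringsAsFactors = FALSE)
  for (g in seq_len(generations)) {
    prev <- gens[[g]]
    gens[[g + 1]] <- data.frame(
      id = paste0("I_", g, "_", seq_len(n)),
      sire = sample(prev$id[prev$sex == "male"], n, replace = TRUE),
      dam = sample(prev$id[prev$sex == "female"], n, replace = TRUE),
      sex = sexes, birth_date = as.character(2000 + g),
      breed = "IDEAL", alive = TRUE, generation = g,
      stringsAsFactors = FALSE)
  }
  finish_sim_ped(do.call(rbind, gens))
}
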