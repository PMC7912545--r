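#' Column dialect for pedigree files
#'
#' Describes how the columns of a tabular studbook file map onto the fields
#' a pedigree needs, and which tokens in the sire/dam columns mean "parent
#' unknown".
#'
#' @param id,sire,dam,sex,birth_date,breed,alive Column names in the file.
#'   `sex`, `birth_date`, `breed` and `alive` may be `NA` if the file lacks
#'   them.
#' @param missing_codes Character tokens (besides an empty cell) that encode
#'   an unknown parent.
#' @return A list of class `ped_dialect`.
#' @export
ped_dialect <- function(id = "id", sire = "sire", dam = "dam",
                        sex = "sex", birth_date = "birth_date",
                        breed = "breed", alive = "alive",
                        missing_codes = c("", "0", "NA", "UNKNOWN")) {
  structure(list(id = id, sire = sire, dam = dam, sex = sex,
                 birth_date = birth_date, breed = breed, alive = alive,
                 missing_codes = missing_codes),
            class = "ped_dialect")
}

norm_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("m", "male", "1", "s", "sire", "stallion")] <- "male"
  out[x %in% c("f", "female", "2", "d", "dam", "mare")] <- "female"
  out
}

# Decimal years since 1970-01-01 (365.25-day years); bare years -> July 1.
parse_birth <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_real_, length(x))
  bare <- grepl("^[0-9]{4}$", x)
  if (any(bare))
    out[bare] <- as.numeric(as.Date(paste0(x[bare], "-07-01"))) / 365.25
  iso <- !bare & !is.na(x) & nzchar(x)
  if (any(iso)) {
    d <- suppressWarnings(as.Date(x[iso]))
    out[iso] <- as.numeric(d) / 365.25
  }
  out
}

#' Construct a validated pedigree from a data frame
#'
#' Normalizes unknown-parent codes, creates phantom founders for dangling
#' parent references (optionally an error), checks id uniqueness, self- and
#' cross-sex parentage, detects parent-link cycles, and returns the records
#' in a stable topological order (parents always precede offspring; ties keep
#' input order).
#'
#' @param df Data frame with at least `id`, `sire`, `dam` columns; optional
#'   `sex`, `birth_date`, `breed`, `alive`.
#' @param missing_codes Tokens meaning "unknown parent".
#' @param on_missing_parent `"phantom"` (create a founder record, with a
#'   warning) or `"error"`.
#' @return An object of class `pedigree`: a data frame with columns `id`,
#'   `sire`, `dam` (NA = unknown), `sex`, `birth` (decimal years), `breed`,
#'   `alive`, plus integer parent indices `sire_idx`, `dam_idx` (0 =
#'   unknown).
#' @export
as_pedigree <- function(df, missing_codes = c("", "0", "NA", "UNKNOWN"),
                        on_missing_parent = c("phantom", "error")) {
  on_missing_parent <- match.arg(on_missing_parent)
  id   <- trimws(as.character(df$id))
  sire <- trimws(as.character(df$sire))
  dam  <- trimws(as.character(df$dam))
  if (any(!nzchar(id) | is.na(id))) stop("empty animal id at row(s): ",
    paste(utils::head(which(!nzchar(id) | is.na(id)), 5), collapse = ", "))
  dup <- id[duplicated(id)]
  if (length(dup)) stop("duplicate animal id(s): ",
                        paste(unique(utils::head(dup, 5)), collapse = ", "))
  sire[is.na(sire) | sire %in% missing_codes] <- NA
  dam[is.na(dam) | dam %in% missing_codes] <- NA
  if (any(!is.na(sire) & sire == id)) stop("animal recorded as its own sire: ",
    id[which(!is.na(sire) & sire == id)[1]])
  if (any(!is.na(dam) & dam == id)) stop("animal recorded as its own dam: ",
    id[which(!is.na(dam) & dam == id)[1]])

  sex <- if (!is.null(df$sex)) norm_sex(df$sex) else rep("unknown", length(id))
  birth <- if (!is.null(df$birth_date)) parse_birth(df$birth_date)
           else rep(NA_real_, length(id))
  breed <- if (!is.null(df$breed)) as.character(df$breed)
           else rep(NA_character_, length(id))
  alive <- if (!is.null(df$alive)) {
    a <- tolower(trimws(as.character(df$alive)))
    a %in% c("true", "t", "1", "yes", "alive")
  } else rep(TRUE, length(id))

  # dangling parent references
  refs <- unique(c(sire[!is.na(sire)], dam[!is.na(dam)]))
  missing_refs <- setdiff(refs, id)
  if (length(missing_refs)) {
    if (on_missing_parent == "error")
      stop("referenced parent(s) with no record: ",
           paste(utils::head(missing_refs, 5), collapse = ", "))
    warning(length(missing_refs),
            " referenced parent(s) had no record; phantom founders created")
    ph_sex <- ifelse(missing_refs %in% sire, "male", "female")
    # breed of a phantom follows its first recorded offspring
    first_off <- match(missing_refs, sire)
    first_off[is.na(first_off)] <- match(missing_refs[is.na(first_off)], dam)
    id    <- c(id, missing_refs)
    sire  <- c(sire, rep(NA, length(missing_refs)))
    dam   <- c(dam, rep(NA, length(missing_refs)))
    sex   <- c(sex, ph_sex)
    birth <- c(birth, rep(NA_real_, length(missing_refs)))
    breed <- c(breed, breed[first_off])
    alive <- c(alive, rep(FALSE, length(missing_refs)))
  }

  # sex consistency with parental role
  si <- match(sire, id)
  di <- match(dam, id)
  bad <- which(sex[si] == "female")
  if (length(bad)) stop("animal recorded as a sire but sexed female: ",
                        sire[bad[1]])
  bad <- which(sex[di] == "male")
  if (length(bad)) stop("animal recorded as a dam but sexed male: ",
                        dam[bad[1]])
  sex[stats::na.omit(unique(si))][] <- "male"
  sex[stats::na.omit(unique(di))][] <- "female"

  ord <- topo_order(si, di, id)
  pos <- order(ord)  # new position of each old row
  ped <- data.frame(id = id, sire = sire, dam = dam, sex = sex,
                    birth = birth, breed = breed, alive = alive,
                    stringsAsFactors = FALSE)[pos, , drop = FALSE]
  rownames(ped) <- NULL
  ped$sire_idx <- match(ped$sire, ped$id, incomparables = NA)
  ped$dam_idx  <- match(ped$dam, ped$id, incomparables = NA)
  ped$sire_idx[is.na(ped$sire_idx)] <- 0L
  ped$dam_idx[is.na(ped$dam_idx)] <- 0L
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Longest-ancestral-path depth per animal with cycle detection (iterative
# DFS); final order = depth, ties broken by input position, which puts every
# parent before its offspring and is stable across reads.
topo_order <- function(si, di, id) {
  n <- length(si)
  depth <- rep(NA_integer_, n)
  state <- integer(n)  # 0 new, 1 in progress, 2 done
  for (root in seq_len(n)) {
    if (state[root] == 2L) next
    stack <- root
    while (length(stack)) {
      v <- stack[length(stack)]
      if (state[v] == 2L) { stack <- stack[-length(stack)]; next }
      parents <- c(si[v], di[v])
      parents <- parents[!is.na(parents)]
      pending <- parents[state[parents] != 2L]
      if (length(pending)) {
        if (any(state[pending] == 1L)) {
          cyc <- pending[state[pending] == 1L][1]
          loop <- stack[which(stack == cyc)[1]:length(stack)]
          stop("parent-link cycle detected: ",
               paste(id[loop], collapse = " -> "), " -> ", id[cyc])
        }
        state[v] <- 1L
        stack <- c(stack, pending)
      } else {
        depth[v] <- if (length(parents)) max(depth[parents]) + 1L else 0L
        state[v] <- 2L
        stack <- stack[-length(stack)]
      }
    }
  }
  depth
}

#' @export
print.pedigree <- function(x, ...) {
  cat("<pedigree> ", nrow(x), " animals (",
      sum(x$sire_idx == 0 & x$dam_idx == 0), " founders, ",
      sum(x$alive), " alive)", sep = "")
  foc <- attr(x, "focal_ids")
  if (!is.null(foc)) cat(" | focal set:", length(foc))
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat("...\n")
  invisible(x)
}

#' Read a pedigree file
#'
#' Reads a delimited studbook file, applies the column dialect and returns a
#' validated, topologically ordered [as_pedigree()] object.
#'
#' @param path File path (CSV by default).
#' @param dialect A [ped_dialect()].
#' @param sep Field separator.
#' @param on_missing_parent See [as_pedigree()].
#' @return A `pedigree`.
#' @export
read_pedigree <- function(path, dialect = ped_dialect(), sep = ",",
                          on_missing_parent = c("phantom", "error")) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", quote = "\"",
                           comment.char = "", check.names = FALSE,
                           fileEncoding = "UTF-8")
  pick <- function(col) if (!is.na(col) && col %in% names(raw)) raw[[col]] else NULL
  df <- data.frame(id = pick(dialect$id), stringsAsFactors = FALSE)
  for (f in c("sire", "dam", "sex", "birth_date", "breed", "alive")) {
    v <- pick(dialect[[f]])
    if (!is.null(v)) df[[f]] <- v
  }
  if (is.null(df$sire) || is.null(df$dam))
    stop("dialect must name id, sire and dam columns present in the file")
  as_pedigree(df, missing_codes = dialect$missing_codes,
              on_missing_parent = on_missing_parent)
}

#' Write a pedigree file
#'
#' Inverse of [read_pedigree()] for the default dialect; unknown parents are
#' written as empty cells and birth as the decimal-year value rounded to the
#' containing date.
#' @param ped A `pedigree`.
#' @param path Output path.
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(id = ped$id,
                    sire = ifelse(is.na(ped$sire), "", ped$sire),
                    dam = ifelse(is.na(ped$dam), "", ped$dam),
                    sex = ped$sex,
                    birth_date = ifelse(is.na(ped$birth), "",
                      as.character(as.Date(round(ped$birth * 365.25),
                                           origin = "1970-01-01"))),
                    breed = ifelse(is.na(ped$breed), "", ped$breed),
                    alive = ped$alive, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Index closure of ids and all their known ancestors.
ancestor_closure <- function(ped, idx) {
  keep <- logical(nrow(ped))
  keep[idx] <- TRUE
  # rows are topologically ordered, so one sweep from high to low index
  # catches every ancestor
  for (i in rev(seq_len(nrow(ped)))) {
    if (!keep[i]) next
    s <- ped$sire_idx[i]; d <- ped$dam_idx[i]
    if (s > 0) keep[s] <- TRUE
    if (d > 0) keep[d] <- TRUE
  }
  which(keep)
}

#' Subset a pedigree by population set or breed
#'
#' `"historical"` keeps everything; `"current"` keeps living animals (the
#' focal set) plus all their ancestors as computational context; any other
#' selector is interpreted as a breed label and keeps that breed plus
#' ancestors. The focal ids are recorded in the `focal_ids` attribute, which
#' downstream reference-population arguments default to.
#'
#' @param ped A `pedigree`.
#' @param selector `"historical"`, `"current"`, or a breed label.
#' @return A `pedigree` with attribute `focal_ids`.
#' @export
subset_population <- function(ped, selector) {
  stopifnot(inherits(ped, "pedigree"), is.character(selector),
            length(selector) == 1)
  if (selector == "historical") {
    attr(ped, "focal_ids") <- ped$id
    return(ped)
  }
  focal <- if (selector == "current") which(ped$alive)
           else which(!is.na(ped$breed) & ped$breed == selector)
  if (!length(focal)) stop("empty population for selector '", selector, "'")
  keep <- ancestor_closure(ped, focal)
  out <- as.data.frame(ped)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out$sire_idx <- match(out$sire, out$id, incomparables = NA)
  out$dam_idx  <- match(out$dam, out$id, incomparables = NA)
  out$sire_idx[is.na(out$sire_idx)] <- 0L
  out$dam_idx[is.na(out$dam_idx)] <- 0L
  class(out) <- c("pedigree", "data.frame")
  attr(out, "focal_ids") <- ped$id[focal]
  out
}

# Focal (reference) row indices of a pedigree: the subset the statistics
# describe. Defaults to the focal_ids attribute, else every record.
focal_indices <- function(ped, reference = NULL) {
  if (is.null(reference)) reference <- attr(ped, "focal_ids")
  if (is.null(reference)) return(seq_len(nrow(ped)))
  idx <- match(reference, ped$id)
  if (anyNA(idx)) stop("reference id(s) not in pedigree: ",
                       paste(utils::head(reference[is.na(idx)], 5),
                             collapse = ", "))
  idx
}
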