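#' Build a trait dictionary
#'
#' A trait dictionary describes the quantitative traits scored in a trial:
#' a short column abbreviation, a human-readable name, measurement units,
#' and the direction of desirability (`goal`) used when traits enter the
#' genotype-ideotype distance index.
#'
#' @param abbr Character vector of unique trait abbreviations (column names
#'   in the plot table, e.g. `"PH"`, `"FW"`).
#' @param name Full trait names; defaults to the abbreviations.
#' @param units Measurement units per trait (free text, may be `NA`).
#' @param goal `"increase"` or `"decrease"` per trait: whether larger or
#'   smaller values are agronomically desirable.
#' @return A tibble with columns `abbr`, `name`, `units`, `goal`.
#' @examples
#' trait_dictionary(c("PH", "FW"), c("Vine length", "Fruit weight"),
#'                  c("cm", "g"))
#' @export
trait_dictionary <- function(abbr, name = abbr, units = NA_character_,
                             goal = "increase") {
  abbr <- as.character(abbr)
  if (anyDuplicated(abbr)) {
    abort(paste0("duplicate trait abbreviation: ",
                 paste(unique(abbr[duplicated(abbr)]), collapse = ", ")))
  }
  recycle_to <- function(x, n) {
    if (!length(x) %in% c(1L, n)) abort("length mismatch in trait dictionary")
    rep_len(as.character(x), n)
  }
  goal <- recycle_to(goal, length(abbr))
  bad <- setdiff(unique(goal), c("increase", "decrease"))
  if (length(bad)) {
    abort(paste0("trait goal must be 'increase' or 'decrease', got: ",
                 paste(bad, collapse = ", ")))
  }
  tibble(
    abbr  = abbr,
    name  = recycle_to(name, length(abbr)),
    units = recycle_to(units, length(abbr)),
    goal  = goal
  )
}

#' Default 17-trait cucumber dictionary
#'
#' The standard descriptor set for cucumber (*Cucumis sativus*) landrace
#' characterisation: vine length, branching, internode distance, phenology
#' (days to male/female flowering, first and mature fruit harvest), leaf
#' dimensions, fruit dimensions and weight, fruit number, yield and
#' hundred-seed weight.  Phenology traits (DM, DFM, FFH, DH) default to
#' `goal = "decrease"` (earliness is desirable); all others to
#' `"increase"`.
#'
#' @return A trait dictionary tibble (see [trait_dictionary()]).
#' @export
cucumber_traits <- function() {
  trait_dictionary(
    abbr = c("PH", "BPP", "DI", "DM", "DFM", "NMF", "NMFF", "LN", "LW",
             "FFH", "FL", "FD", "FW", "NFP", "DH", "YP", "HSW"),
    name = c("Vine length", "Primary branches per plant",
             "Internode distance", "Days to male flower",
             "Days to female flower", "Node of first male flower",
             "Node of first female flower", "Leaf length", "Leaf width",
             "Days to first fruit harvest", "Fruit length", "Fruit width",
             "Fruit weight", "Fruits per plant",
             "Days to mature fruit harvest", "Yield per plant",
             "Hundred-seed weight"),
    units = c("cm", "count", "cm", "days", "days", "count", "count", "cm",
              "cm", "days", "cm", "cm", "g", "count", "days", "kg", "g"),
    goal = c("increase", "increase", "increase", "decrease", "decrease",
             "increase", "increase", "increase", "increase", "decrease",
             "increase", "increase", "increase", "increase", "decrease",
             "increase", "increase")
  )
}

#' Construct an augmented-RCBD trial object
#'
#' An augmented randomised complete block design replicates a small set of
#' check varieties in every block while each unreplicated test entry occurs
#' in exactly one block.  The constructor validates that layout: every
#' check present exactly once per block, every test exactly once overall,
#' at least two blocks and two checks (so the check-by-block residual has
#' at least one degree of freedom), and check/test identifiers disjoint.
#'
#' @param plots A data frame with columns `block`, `genotype`, `role`
#'   (`"check"` or `"test"`) plus one numeric column per trait
#'   abbreviation.  Missing trait values (`NA`) are allowed and excluded
#'   per trait downstream; present values must be finite.
#' @param traits A trait dictionary (see [trait_dictionary()]), or a
#'   character vector of abbreviations.  Defaults to all non-design
#'   columns of `plots`.
#' @return An object of class `augmented_trial`: a list with elements
#'   `plots` (tibble in canonical block/role/genotype order), `traits`,
#'   `blocks`, `checks`, `tests`.
#' @examples
#' plots <- expand.grid(block = c("B1", "B2"), genotype = c("C1", "C2"),
#'                      stringsAsFactors = FALSE)
#' plots$role <- "check"
#' plots$PH <- c(10, 14, 12, 16)
#' plots <- rbind(plots, data.frame(block = c("B1", "B2"),
#'                                  genotype = c("T1", "T2"),
#'                                  role = "test", PH = c(20, 25)))
#' augmented_trial(plots)
#' @export
augmented_trial <- function(plots, traits = NULL) {
  plots <- as_tibble(plots)
  required <- c("block", "genotype", "role")
  missing_cols <- setdiff(required, names(plots))
  if (length(missing_cols)) {
    abort(paste0("format error: plot table lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "phenodiv_format_error")
  }
  if (is.null(traits)) traits <- setdiff(names(plots), required)
  if (is.character(traits)) traits <- trait_dictionary(traits)
  stopifnot(is.data.frame(traits))
  missing_traits <- setdiff(traits$abbr, names(plots))
  if (length(missing_traits)) {
    abort(paste0("format error: plot table lacks trait column(s): ",
                 paste(missing_traits, collapse = ", ")),
          class = "phenodiv_format_error")
  }

  plots$block <- as.character(plots$block)
  plots$genotype <- as.character(plots$genotype)
  plots$role <- as.character(plots$role)
  bad_role <- setdiff(unique(plots$role), c("check", "test"))
  if (length(bad_role)) {
    abort(paste0("layout error: unknown role(s): ",
                 paste(bad_role, collapse = ", ")),
          class = "phenodiv_layout_error")
  }
  for (tr in traits$abbr) {
    v <- plots[[tr]]
    if (!is.numeric(v)) {
      abort(paste0("format error: trait column ", tr, " is not numeric"),
            class = "phenodiv_format_error")
    }
    if (any(!is.na(v) & !is.finite(v))) {
      abort(paste0("layout error: non-finite value in trait ", tr),
            class = "phenodiv_layout_error")
    }
  }

  blocks <- sort(unique(plots$block))
  checks <- sort(unique(plots$genotype[plots$role == "check"]))
  tests  <- sort(unique(plots$genotype[plots$role == "test"]))

  if (length(blocks) < 2) {
    abort("layout error: an augmented RCBD needs at least 2 blocks",
          class = "phenodiv_layout_error")
  }
  if (length(checks) < 2) {
    abort("layout error: at least 2 replicated checks are required",
          class = "phenodiv_layout_error")
  }
  overlap <- intersect(checks, tests)
  if (length(overlap)) {
    abort(paste0("layout error: genotype(s) appear as both check and test: ",
                 paste(overlap, collapse = ", ")),
          class = "phenodiv_layout_error")
  }
  # each check exactly once in every block
  chk <- plots[plots$role == "check", c("block", "genotype")]
  tab <- table(factor(chk$genotype, levels = checks),
               factor(chk$block, levels = blocks))
  if (any(tab != 1L)) {
    idx <- which(tab != 1L, arr.ind = TRUE)[1, ]
    abort(paste0("layout error: check ", checks[idx[1]],
                 " occurs ", tab[idx[1], idx[2]], " time(s) in block ",
                 blocks[idx[2]], " (expected exactly 1)"),
          class = "phenodiv_layout_error")
  }
  # each test exactly once in exactly one block
  tst <- plots$genotype[plots$role == "test"]
  dup <- unique(tst[duplicated(tst)])
  if (length(dup)) {
    abort(paste0("layout error: test entry replicated: ",
                 paste(dup, collapse = ", ")),
          class = "phenodiv_layout_error")
  }

  plots <- arrange(plots, .data$block, .data$role, .data$genotype)
  structure(
    list(plots = plots[, c(required, traits$abbr)],
         traits = as_tibble(traits),
         blocks = blocks, checks = checks, tests = tests),
    class = "augmented_trial"
  )
}

#' @export
print.augmented_trial <- function(x, ...) {
  cat("Augmented RCBD trial\n")
  cat("  blocks: ", length(x$blocks),
      "  checks: ", length(x$checks),
      "  tests: ", length(x$tests),
      "  plots: ", nrow(x$plots), "\n", sep = "")
  cat("  traits: ", paste(x$traits$abbr, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Genotype identifiers of a trial
#'
#' @param trial An [augmented_trial()] object.
#' @return Character vector: checks then tests, each sorted.
#' @export
trial_genotypes <- function(trial) {
  stopifnot(inherits(trial, "augmented_trial"))
  c(trial$checks, trial$tests)
}

sniff_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read an augmented trial from a delimited file
#'
#' Expects a UTF-8 CSV or TSV (delimiter sniffed from the header row) with
#' columns `block`, `genotype`, `role` and one column per trait
#' abbreviation, plus a YAML trait dictionary.
#'
#' @param path Path to the plot-level CSV/TSV file.
#' @param dictionary Path to a YAML trait dictionary (see
#'   [read_trait_dictionary()]), or a trait dictionary tibble, or `NULL`
#'   to infer traits from the non-design columns.
#' @return An [augmented_trial()] object.
#' @export
read_trial <- function(path, dictionary = NULL) {
  delim <- sniff_delim(path)
  plots <- readr::read_delim(path, delim = delim, comment = "#",
                             show_col_types = FALSE, progress = FALSE)
  traits <- if (is.character(dictionary)) read_trait_dictionary(dictionary)
            else dictionary
  augmented_trial(plots, traits)
}

#' Write an augmented trial to TSV
#'
#' Values are written at full (round-trippable) precision so that
#' `read_trial(write_trial(x))` reproduces the trial exactly.
#'
#' @param trial An [augmented_trial()] object.
#' @param path Output TSV path.
#' @param dictionary Optional path to also write the YAML trait dictionary.
#' @return `trial`, invisibly.
#' @export
write_trial <- function(trial, path, dictionary = NULL) {
  stopifnot(inherits(trial, "augmented_trial"))
  readr::write_tsv(trial$plots, path, progress = FALSE)
  if (!is.null(dictionary)) write_trait_dictionary(trial$traits, dictionary)
  invisible(trial)
}

#' Read / write a YAML trait dictionary
#'
#' The YAML layout is a top-level `traits:` list with `abbr`, `name`,
#' `units` and `goal` entries per trait.
#'
#' @param path YAML file path.
#' @return A trait dictionary tibble.
#' @export
read_trait_dictionary <- function(path) {
  y <- yaml::read_yaml(path)
  entries <- y$traits %||% y
  tr <- purrr::map_dfr(entries, function(e) {
    tibble(abbr = as.character(e$abbr),
           name = as.character(e$name %||% e$abbr),
           units = as.character(e$units %||% NA_character_),
           goal = as.character(e$goal %||% "increase"))
  })
  trait_dictionary(tr$abbr, tr$name, tr$units, tr$goal)
}

#' @rdname read_trait_dictionary
#' @param traits A trait dictionary tibble.
#' @export
write_trait_dictionary <- function(traits, path) {
  entries <- purrr::pmap(traits, function(abbr, name, units, goal) {
    e <- list(abbr = abbr, name = name, goal = goal)
    if (!is.na(units)) e$units <- units
    e
  })
  yaml::write_yaml(list(traits = entries), path)
  invisible(traits)
}

# ---- qualitative descriptors ------------------------------------------------

#' Build a qualitative descriptor dictionary
#'
#' Each descriptor has an ordered list of defined states (integer code +
#' label).  The number of *defined* states, `k`, normalises the
#' Shannon-Weaver diversity index, so states that happen not to be observed
#' in a particular collection still count.
#'
#' @param name Descriptor names (unique).
#' @param states A list, one element per descriptor, each a data frame or
#'   tibble with columns `code` (integer) and `label`.
#' @return A tibble with columns `name`, `states` (list-column), `k`.
#' @examples
#' descriptor_dictionary("Seed colour",
#'                       list(data.frame(code = 1:2,
#'                                       label = c("White", "Cream"))))
#' @export
descriptor_dictionary <- function(name, states) {
  name <- as.character(name)
  if (anyDuplicated(name)) abort("duplicate descriptor name")
  stopifnot(length(states) == length(name))
  states <- purrr::map(states, function(s) {
    s <- as_tibble(s)
    stopifnot(all(c("code", "label") %in% names(s)))
    s$code <- as.integer(s$code)
    if (nrow(s) < 1) abort("descriptor must define at least one state")
    if (anyDuplicated(s$code)) abort("duplicate state code within descriptor")
    s[, c("code", "label")]
  })
  tibble(name = unname(name), states = unname(states),
         k = unname(purrr::map_int(states, nrow)))
}

#' Read / write a YAML descriptor dictionary
#'
#' YAML layout: top-level `descriptors:` list, each with `name:` and a
#' `states:` list of `{code, label}` pairs.
#'
#' @param path YAML file path.
#' @return A descriptor dictionary tibble (see [descriptor_dictionary()]).
#' @export
read_descriptor_dictionary <- function(path) {
  y <- yaml::read_yaml(path)
  entries <- y$descriptors %||% y
  descriptor_dictionary(
    purrr::map_chr(entries, "name"),
    purrr::map(entries, function(e) {
      tibble(code = purrr::map_int(e$states, ~ as.integer(.x$code)),
             label = purrr::map_chr(e$states, "label"))
    })
  )
}

#' @rdname read_descriptor_dictionary
#' @param descriptors A descriptor dictionary tibble.
#' @export
write_descriptor_dictionary <- function(descriptors, path) {
  entries <- purrr::pmap(descriptors[, c("name", "states")],
    function(name, states) {
      list(name = name,
           states = purrr::pmap(states, function(code, label) {
             list(code = as.integer(code), label = label)
           }))
    })
  yaml::write_yaml(list(descriptors = entries), path)
  invisible(descriptors)
}

#' Construct a validated genotype-by-descriptor table
#'
#' @param observations A data frame with a `genotype` column and one
#'   integer-coded column per descriptor (column names must match
#'   descriptor names in the dictionary; names with spaces are allowed).
#' @param descriptors A descriptor dictionary (see
#'   [descriptor_dictionary()]).
#' @return An object of class `qualitative_table`: list with `observations`
#'   (tibble) and `descriptors`.
#' @export
qualitative_table <- function(observations, descriptors) {
  observations <- as_tibble(observations)
  if (!"genotype" %in% names(observations)) {
    abort("format error: observations lack a genotype column",
          class = "phenodiv_format_error")
  }
  observations$genotype <- as.character(observations$genotype)
  if (anyDuplicated(observations$genotype)) {
    abort("layout error: duplicated genotype rows",
          class = "phenodiv_layout_error")
  }
  missing_d <- setdiff(descriptors$name, names(observations))
  if (length(missing_d)) {
    abort(paste0("format error: observations lack descriptor column(s): ",
                 paste(missing_d, collapse = ", ")),
          class = "phenodiv_format_error")
  }
  for (i in seq_len(nrow(descriptors))) {
    d <- descriptors$name[i]
    codes <- descriptors$states[[i]]$code
    obs <- observations[[d]]
    bad <- setdiff(unique(obs[!is.na(obs)]), codes)
    if (length(bad)) {
      abort(paste0("validation error: descriptor '", d,
                   "' has undefined state code(s): ",
                   paste(bad, collapse = ", ")),
            class = "phenodiv_validation_error")
    }
    observations[[d]] <- as.integer(obs)
  }
  observations <- arrange(observations, .data$genotype)
  structure(
    list(observations = observations[, c("genotype", descriptors$name)],
         descriptors = descriptors),
    class = "qualitative_table"
  )
}

#' @export
print.qualitative_table <- function(x, ...) {
  cat("Qualitative descriptor table\n")
  cat("  genotypes: ", nrow(x$observations),
      "  descriptors: ", nrow(x$descriptors), "\n", sep = "")
  invisible(x)
}

#' Read a coded qualitative table from CSV/TSV
#'
#' @param path CSV/TSV of one row per genotype, integer state codes.
#' @param dictionary Path to a YAML descriptor dictionary or a dictionary
#'   tibble.
#' @return A [qualitative_table()] object.
#' @export
read_qualitative <- function(path, dictionary) {
  delim <- sniff_delim(path)
  obs <- readr::read_delim(path, delim = delim, comment = "#",
                           show_col_types = FALSE, progress = FALSE)
  d <- if (is.character(dictionary)) read_descriptor_dictionary(dictionary)
       else dictionary
  qualitative_table(obs, d)
}

#' Write a qualitative table to TSV
#'
#' @param qual A [qualitative_table()] object.
#' @param path Output TSV path.
#' @param dictionary Optional path to also write the YAML descriptor
#'   dictionary.
#' @return `qual`, invisibly.
#' @export
write_qualitative <- function(qual, path, dictionary = NULL) {
  stopifnot(inherits(qual, "qualitative_table"))
  readr::write_tsv(qual$observations, path, progress = FALSE)
  if (!is.null(dictionary)) {
    write_descriptor_dictionary(qual$descriptors, dictionary)
  }
  invisible(qual)
}
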