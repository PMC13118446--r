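#' Default dihydropyridine calcium-channel-blocker dictionary
#'
#' Long-format drug dictionary: one row per (canonical ingredient,
#' synonym) with a class tag. The class column marks ATC C08CA
#' dihydropyridine ingredients (`"class"`), of which the four study
#' drugs are additionally tagged `"target"`. Brand-name synonym lists
#' cover the common US brands; users can extend or replace the
#' dictionary with any tibble of the same shape.
#'
#' @return Tibble with columns `ingredient`, `synonym`, `class`
#'   (`"target"`, `"class"` or `"other"`).
#' @export
dhp_dictionary <- function() {
  entry <- function(ingredient, synonyms, class) {
    tibble(ingredient = ingredient,
           synonym = toupper(c(ingredient, synonyms)), class = class)
  }
  targets <- bind_rows(
    entry("amlodipine", c("NORVASC", "KATERZIA", "NORLIQVA"), "target"),
    entry("felodipine", c("PLENDIL"), "target"),
    entry("nicardipine", c("CARDENE", "CARDENE SR", "CARDENE IV"), "target"),
    entry("nifedipine", c("PROCARDIA", "PROCARDIA XL", "ADALAT",
                          "ADALAT CC", "AFEDITAB CR"), "target")
  )
  class_only <- bind_rows(
    entry("isradipine", c("DYNACIRC"), "class"),
    entry("lacidipine", character(0), "class"),
    entry("lercanidipine", c("ZANIDIP"), "class"),
    entry("manidipine", character(0), "class"),
    entry("nilvadipine", character(0), "class"),
    entry("nimodipine", c("NIMOTOP", "NYMALIZE"), "class"),
    entry("nisoldipine", c("SULAR"), "class"),
    entry("nitrendipine", character(0), "class"),
    entry("clevidipine", c("CLEVIPREX"), "class"),
    entry("benidipine", character(0), "class"),
    entry("cilnidipine", character(0), "class"),
    entry("barnidipine", character(0), "class")
  )
  bind_rows(targets, class_only) |> distinct()
}

#' Target ingredients of a dictionary
#' @param dictionary A dictionary tibble as from [dhp_dictionary()].
#' @return Character vector of canonical target ingredients.
#' @export
target_drugs <- function(dictionary = dhp_dictionary()) {
  sort(unique(dictionary$ingredient[dictionary$class == "target"]))
}

#' Class-member ingredients of a dictionary
#' @inheritParams target_drugs
#' @return Character vector of ingredients in the comparison class
#'   (targets included).
#' @export
class_drugs <- function(dictionary = dhp_dictionary()) {
  sort(unique(dictionary$ingredient[dictionary$class %in% c("target", "class")]))
}

# Salt/ester suffixes stripped from active-ingredient tokens before
# dictionary matching; configurable via options(faersignal.salt_suffixes=).
default_salt_suffixes <- function() {
  c("BESYLATE", "BESILATE", "MALEATE", "MESYLATE", "MESILATE",
    "HYDROCHLORIDE", "HCL", "BENZOATE", "SODIUM", "POTASSIUM",
    "CALCIUM", "TARTRATE", "SUCCINATE", "FUMARATE", "CITRATE",
    "SULFATE", "SULPHATE", "ACETATE", "PHOSPHATE", "NITRATE",
    "OXALATE", "BROMIDE", "CHLORIDE")
}

normalize_drug_string <- function(x) {
  x <- toupper(trimws(x))
  x <- gsub("\\s+", " ", x)
  x
}

# Split a combination-product string into component tokens: FAERS uses
# '\' and '+' (and occasionally ';' or '/') between ingredients.
split_components <- function(x) {
  strsplit(x, "\\s*[\\\\+;/]\\s*")[[1]]
}

strip_salt <- function(component, suffixes) {
  words <- strsplit(trimws(component), " ", fixed = TRUE)[[1]]
  while (length(words) > 1 && words[length(words)] %in% suffixes) {
    words <- words[-length(words)]
  }
  paste(words, collapse = " ")
}

#' Match a drug mention against a dictionary
#'
#' Matches the active-ingredient string (`prod_ai`) and the verbatim
#' drug name (`drugname`) against a dictionary's synonym lists. Both are
#' upper-cased and trimmed; combination products are split on
#' '\\', '+', ';' and '/'; salt/ester suffixes (besylate, maleate, ...)
#' are stripped from each component before comparison. Matching is
#' deterministic and case-insensitive.
#'
#' @param drugname Verbatim drug name (may be `NA`).
#' @param prod_ai Active-ingredient string (may be `NA`).
#' @param dictionary Dictionary tibble (`ingredient`, `synonym`, `class`).
#' @return Character vector of matched canonical ingredients (possibly
#'   empty).
#' @examples
#' match_drug(NA, "AMLODIPINE BESYLATE")
#' match_drug("NORVASC", NA)
#' @export
match_drug <- function(drugname, prod_ai, dictionary = dhp_dictionary()) {
  suffixes <- getOption("faersignal.salt_suffixes", default_salt_suffixes())
  syn <- dictionary$synonym
  candidates <- character(0)
  for (s in c(prod_ai, drugname)) {
    if (is.na(s) || !nzchar(s)) next
    comps <- split_components(normalize_drug_string(s))
    comps <- vapply(comps, strip_salt, character(1), suffixes = suffixes)
    candidates <- c(candidates, comps)
  }
  hits <- dictionary$ingredient[syn %in% candidates]
  sort(unique(hits))
}

# Vectorised dictionary matcher for whole DRUG tables: returns the
# input tibble with a list-free long join (one row per match).
match_drug_table <- function(drug_tbl, dictionary) {
  suffixes <- getOption("faersignal.salt_suffixes", default_salt_suffixes())
  n <- nrow(drug_tbl)
  dn <- if ("drugname" %in% names(drug_tbl)) drug_tbl$drugname else
    rep(NA_character_, n)
  ai <- if ("prod_ai" %in% names(drug_tbl)) drug_tbl$prod_ai else
    rep(NA_character_, n)
  # resolve each distinct raw string once (normalisation included)
  uniq <- unique(c(ai, dn))
  uniq <- uniq[!is.na(uniq) & nzchar(uniq)]
  resolved <- purrr::map(normalize_drug_string(uniq), function(s) {
    comps <- split_components(s)
    comps <- vapply(comps, strip_salt, character(1), suffixes = suffixes)
    unique(dictionary$ingredient[dictionary$synonym %in% comps])
  })
  # NA indices yield NULL list elements, which unlist()/lengths() skip
  li_ai <- resolved[match(ai, uniq)]
  li_dn <- resolved[match(dn, uniq)]
  rows <- c(rep(seq_len(n), lengths(li_ai)), rep(seq_len(n), lengths(li_dn)))
  ing <- c(as.character(unlist(li_ai)), as.character(unlist(li_dn)))
  if (length(rows) == 0) {
    return(drug_tbl[0, ] |> mutate(ingredient = character(0)))
  }
  ing_idx <- match(ing, unique(dictionary$ingredient))
  keep <- !duplicated(rows * (length(unique(dictionary$ingredient)) + 1) +
                        ing_idx)
  drug_tbl[rows[keep], ] |> mutate(ingredient = ing[keep])
}
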