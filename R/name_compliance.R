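#' Load a regulatory trade-name rule table
#'
#' A name rule maps one normalized trade name to a set of allowed taxa,
#' each constraint carrying its rank explicitly (`species`, `genus` or
#' `family`). Duplicate trade-name keys are merged by union of their
#' allowed taxa. The `listed` flag records whether the name itself appears
#' in the regulatory list (names only footnoted in the source survey carry
#' `listed = FALSE` but are still evaluated).
#'
#' @param path Path to a TSV or YAML file with columns/fields
#'   `trade_name`, `rank`, `taxon`, `listed`, `source`, or a data frame
#'   with those columns.
#' @return A tibble of class `name_rules` keyed by normalized `trade_name`.
#' @export
load_name_rules <- function(path) {
  if (is.data.frame(path)) {
    rules <- tibble::as_tibble(path)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML rule files")
    }
    rows <- yaml::read_yaml(path)
    rules <- purrr::map_dfr(rows, tibble::as_tibble)
  } else {
    rules <- readr::read_tsv(path, show_col_types = FALSE)
  }
  needed <- c("trade_name", "rank", "taxon")
  stopifnot(all(needed %in% names(rules)))
  if (!"listed" %in% names(rules)) rules$listed <- TRUE
  if (!"source" %in% names(rules)) rules$source <- NA_character_
  bad_rank <- setdiff(unique(rules$rank), c("species", "genus", "family"))
  if (length(bad_rank)) {
    stop("unknown rank token(s): ", paste(bad_rank, collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(rules$taxon) | is.na(rules$taxon))) {
    stop("empty taxon in name-rule table", call. = FALSE)
  }
  rules$trade_name <- normalize_name(rules$trade_name)
  rules$listed <- as.logical(rules$listed)
  out <- dplyr::distinct(rules, .data$trade_name, .data$rank, .data$taxon,
                         .keep_all = TRUE)
  class(out) <- c("name_rules", class(out))
  out
}

#' Default trade-name rules reproducing the Italian MD name semantics
#'
#' The packaged rule table encodes the trade-name semantics of the Italian
#' ministerial decree n.19105 of 22 September 2017 as applied in the
#' packaged sushi-survey fixture: "tuna"/"red tuna"/"maguro" declare
#' Thunnus thynnus only, "yellowfin tuna" declares T. albacares, tobiko and
#' flying-fish-egg names declare the flying-fish genera Hirundichthys and
#' Cheilopogon (footnoted as absent from the decree list, hence
#' `listed = FALSE`), "ikura"/"salmon eggs" declare the genus Oncorhynchus,
#' and so on.
#'
#' @return A `name_rules` tibble.
#' @export
default_name_rules <- function() {
  load_name_rules(system.file("extdata", "md_name_rules.tsv",
                              package = "coiauth", mustWork = TRUE))
}

#' Default species taxonomy for the packaged survey
#'
#' Genus and family of every species occurring in the packaged fixture
#' (declared or identified), used for genus- and family-rank rule
#' evaluation and as the taxonomy of the bundled reference panel.
#'
#' @return A tibble: `species`, `genus`, `family`.
#' @export
default_taxonomy <- function() {
  readr::read_tsv(system.file("extdata", "panel_taxonomy.tsv",
                              package = "coiauth", mustWork = TRUE),
                  show_col_types = FALSE)
}

# Split a menu label into candidate lookup parts: the full normalized
# label, parenthetical content, the text outside parentheses, and the
# pieces of compound labels joined by "/" or "or".
label_parts <- function(label) {
  lab <- normalize_name(label)
  inside <- unlist(regmatches(lab, gregexpr("\\(([^)]*)\\)", lab)))
  inside <- gsub("[()]", "", inside)
  outside <- normalize_name(gsub("\\([^)]*\\)", " ", lab))
  pieces <- unlist(strsplit(c(lab, inside, outside), "/| or |,"))
  unique(normalize_name(pieces[nzchar(normalize_name(pieces))]))
}

#' Resolve a menu label to the taxa it lawfully declares
#'
#' Looks the normalized label up in the rule set; compound labels (parts
#' joined by "or", "/" or parentheses) resolve to the union of each
#' resolvable part's taxa. A label none of whose parts has a rule is
#' unlisted.
#'
#' @param menu_label Character label as printed on the menu.
#' @param rules A `name_rules` tibble (default [default_name_rules()]).
#' @return A list with `constraints` (tibble `rank`, `taxon`, `listed`) and
#'   `matched` (FALSE when the label has no rule).
#' @export
#' @examples
#' resolve_declared("sea bream or common bass")$constraints
resolve_declared <- function(menu_label, rules = default_name_rules()) {
  parts <- label_parts(menu_label)
  hit <- dplyr::filter(rules, .data$trade_name %in% parts)
  list(
    constraints = dplyr::distinct(
      tibble::tibble(rank = hit$rank, taxon = hit$taxon, listed = hit$listed)),
    matched = nrow(hit) > 0
  )
}

# Parse the printed "scientific name of declared species" column into
# taxon constraints. Binomials become species-rank constraints,
# "Genus sp"/"spp" becomes a genus-rank constraint, and anything else
# (e.g. "salmon eggs") is looked up as a trade name.
parse_declared_names <- function(declared, rules = default_name_rules()) {
  if (is.na(declared) || !nzchar(declared)) {
    return(tibble::tibble(rank = character(), taxon = character(),
                          listed = logical()))
  }
  tokens <- unlist(strsplit(declared, "/"))
  tokens <- trimws(gsub("[*°]", "", tokens))
  tokens <- tokens[nzchar(tokens)]
  purrr::map_dfr(tokens, function(tok) {
    if (grepl("^[A-Z][a-z-]+ spp?\\.?$", tok)) {
      tibble::tibble(rank = "genus", taxon = sub(" .*$", "", tok), listed = TRUE)
    } else if (grepl("^[A-Z][a-z-]+ [a-z-]+$", tok)) {
      tibble::tibble(rank = "species", taxon = tok, listed = TRUE)
    } else {
      res <- resolve_declared(tok, rules)
      res$constraints
    }
  })
}

# Does an identified binomial satisfy one taxon constraint?
satisfies_constraint <- function(species, rank, taxon, taxonomy = NULL) {
  switch(rank,
    species = identical(species, taxon),
    genus = identical(genus_of(species), taxon),
    family = {
      if (is.null(taxonomy)) {
        stop("a family-rank constraint requires a taxonomy table", call. = FALSE)
      }
      fam <- taxonomy$family[match(species, taxonomy$species)]
      if (is.na(fam)) {
        stop("species '", species, "' not present in the taxonomy table",
             call. = FALSE)
      }
      identical(fam, taxon)
    },
    stop("unknown rank: ", rank, call. = FALSE)
  )
}

#' Map a menu label to a product category
#'
#' Categories follow the survey design (white fish, tuna and roe were the
#' sampled targets): tuna for tuna/maguro labels, white fish for sea
#' bream/common bass labels, roe for tobiko, flying-fish egg, ikura and
#' other roe labels, and `other` for the rest (e.g. anago eel, kajiki
#' swordfish).
#'
#' @param menu_label Character vector of labels.
#' @return Character vector over `{white_fish, tuna, roe, other}`.
#' @export
categorize_label <- function(menu_label) {
  lab <- normalize_name(menu_label)
  dplyr::case_when(
    stringr::str_detect(lab, "tuna|maguro") ~ "tuna",
    stringr::str_detect(lab, "bream|bass") ~ "white_fish",
    stringr::str_detect(lab, "tobiko|ikura|roe|egg") ~ "roe",
    TRUE ~ "other"
  )
}

#' Call misdescription per product
#'
#' A product is misdescribed when no match is found among the menu name,
#' the scientific name(s) it lawfully declares under the rule set, the
#' printed declared scientific name, and the species identified by DNA
#' barcoding. Concretely: the identified species is tested against the
#' union of the constraints derived from the declared-name column and from
#' the menu-label rules; satisfying any one of them makes the product
#' compliant. Products without an assigned species call are `unresolved`;
#' products for which no constraint can be derived at all are
#' `unlisted_name`.
#'
#' @param products A data frame with columns `sample_code`, `menu_label`
#'   and optionally `declared_name` (the printed declared scientific
#'   name(s), "/"-separated).
#' @param calls A data frame with columns `sample_code`, `status`,
#'   `species` (per-product consensus calls, e.g.
#'   `assign_species()$product_calls`).
#' @param rules A `name_rules` tibble.
#' @param taxonomy Species taxonomy (tibble `species`, `genus`, `family`)
#'   for genus/family-rank evaluation; default [default_taxonomy()].
#' @return A tibble: `sample_code`, `menu_label`, `declared_name`,
#'   `identified_species`, `verdict`
#'   (`compliant`/`misdescribed`/`unlisted_name`/`unresolved`),
#'   `label_listed` (the label has a rule), `rationale`.
#' @export
call_compliance <- function(products, calls, rules = default_name_rules(),
                            taxonomy = default_taxonomy()) {
  stopifnot(is.data.frame(products), is.data.frame(calls),
            all(c("sample_code", "menu_label") %in% names(products)),
            all(c("sample_code", "status", "species") %in% names(calls)))
  if (!"declared_name" %in% names(products)) products$declared_name <- NA_character_
  missing <- setdiff(products$sample_code, calls$sample_code)
  if (length(missing)) {
    stop("no species call for product(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- dplyr::left_join(
    tibble::as_tibble(products),
    dplyr::select(calls, "sample_code", "status", "species"),
    by = "sample_code")
  purrr::map_dfr(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    lab <- resolve_declared(row$menu_label, rules)
    decl <- parse_declared_names(row$declared_name, rules)
    constraints <- dplyr::distinct(dplyr::bind_rows(decl, lab$constraints))
    if (!identical(row$status, "assigned")) {
      verdict <- "unresolved"
      rationale <- paste0("no assigned species call (status: ", row$status, ")")
    } else if (nrow(constraints) == 0) {
      verdict <- "unlisted_name"
      rationale <- paste0("menu label '", row$menu_label,
                          "' has no name rule and no parseable declared name")
    } else {
      ok <- purrr::pmap_lgl(constraints[c("rank", "taxon")], function(rank, taxon) {
        satisfies_constraint(row$species, rank, taxon, taxonomy)
      })
      if (any(ok)) {
        hit <- constraints[which(ok)[1], ]
        verdict <- "compliant"
        rationale <- paste0("identified ", row$species, " satisfies ", hit$rank,
                            "-rank constraint ", hit$taxon)
      } else {
        verdict <- "misdescribed"
        rationale <- paste0("identified ", row$species,
                            " matches none of the declared taxa: ",
                            paste(constraints$taxon, collapse = ", "))
      }
    }
    tibble::tibble(
      sample_code = row$sample_code,
      menu_label = row$menu_label,
      declared_name = row$declared_name,
      identified_species = if (identical(row$status, "assigned")) row$species else NA_character_,
      verdict = verdict,
      label_listed = lab$matched,
      rationale = rationale
    )
  })
}
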