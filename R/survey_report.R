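fixture_md5 <- c(
  survey_north.tsv = "0f268ebd0b3bcbcd9e012937314d63c7",
  survey_central.tsv = "887c2603cdbf52edcb885889994f46e4",
  survey_south.tsv = "b9a5dcf5aef2aa6ecf7c63600ffa3356"
)

#' Load the packaged sushi-survey fixture tables
#'
#' Machine-readable transcription of the 60-product Italian sushi survey
#' (19 Northern, 20 Central and 21 Southern products): per product the
#' menu label, the declared scientific name(s), the species identified by
#' COI barcoding with its percent identity, the number of processed
#' replicate extractions (printed in brackets in the source tables) and
#' the misdescription marking (printed in bold). File checksums are
#' verified to guard against silent edits.
#'
#' @param region `"all"` (default), `"north"`, `"central"` or `"south"`.
#' @return A tibble with one row per product.
#' @export
#' @examples
#' nrow(load_fixture())          # 60
#' nrow(load_fixture("central")) # 20
load_fixture <- function(region = c("all", "north", "central", "south")) {
  region <- match.arg(region)
  files <- switch(region,
    all = names(fixture_md5),
    north = "survey_north.tsv",
    central = "survey_central.tsv",
    south = "survey_south.tsv")
  paths <- system.file("extdata", files, package = "coiauth", mustWork = TRUE)
  sums <- unname(tools::md5sum(paths))
  if (!identical(sums, unname(fixture_md5[files]))) {
    stop("fixture checksum mismatch for: ",
         paste(files[sums != fixture_md5[files]], collapse = ", "),
         call. = FALSE)
  }
  purrr::map_dfr(paths, readr::read_tsv, comment = "#",
                 show_col_types = FALSE)
}

#' Stratified misdescription statistics
#'
#' Computes per-product misdescription rates for every stratum of
#' region x retail type x category, including `all` wildcard levels on
#' each axis (so the row `region = "north", retail_type = "all",
#' category = "tuna"` is the Northern tuna rate). Unresolved verdicts are
#' excluded from both numerator and denominator with a message. Displayed
#' rates are rounded half-up.
#'
#' @param verdicts A [call_compliance()] tibble (`sample_code`, `verdict`).
#' @param products A product table with `sample_code`, `region`,
#'   `retail_type`, `category` and optionally `processed_replicates` and
#'   `identity_pct` columns (e.g. [load_fixture()]).
#' @param calls Optional per-product species calls (`sample_code`,
#'   `species`) used for the species inventory; when `NULL`, an
#'   `identified_species` column of `products` is used if present.
#' @return An object of class `survey_summary`: a list with `strata`
#'   (tibble of n_products, n_misdescribed, rate_pct, rate_pct_rounded per
#'   stratum), `species_inventory`, `identity_min`, `identity_max`,
#'   `n_sequences_processed`, `n_unresolved`.
#' @export
stratified_rates <- function(verdicts, products, calls = NULL) {
  stopifnot(all(c("sample_code", "verdict") %in% names(verdicts)),
            all(c("sample_code", "region", "retail_type", "category")
                %in% names(products)))
  missing <- setdiff(products$sample_code, verdicts$sample_code)
  if (length(missing)) {
    stop("product(s) without a verdict: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(products), "sample_code", "region",
                  "retail_type", "category",
                  dplyr::any_of(c("processed_replicates", "identity_pct",
                                  "identified_species"))),
    dplyr::select(verdicts, "sample_code", "verdict"),
    by = "sample_code")
  n_unres <- sum(df$verdict == "unresolved")
  if (n_unres > 0) {
    message(n_unres, " unresolved product(s) excluded from rate denominators")
  }
  df <- dplyr::filter(df, .data$verdict != "unresolved")

  one_level <- function(x) sort(unique(x))
  grid <- tidyr::expand_grid(
    region = c("all", one_level(df$region)),
    retail_type = c("all", one_level(df$retail_type)),
    category = c("all", one_level(df$category)))
  strata <- purrr::pmap_dfr(grid, function(region, retail_type, category) {
    sel <- df
    if (region != "all") sel <- sel[sel$region == region, ]
    if (retail_type != "all") sel <- sel[sel$retail_type == retail_type, ]
    if (category != "all") sel <- sel[sel$category == category, ]
    n <- nrow(sel)
    k <- sum(sel$verdict == "misdescribed")
    tibble::tibble(
      region = region, retail_type = retail_type, category = category,
      n_products = n, n_misdescribed = k,
      rate_pct = if (n > 0) 100 * k / n else NA_real_,
      rate_pct_rounded = if (n > 0) round_half_up(100 * k / n) else NA_real_)
  })
  strata <- dplyr::filter(strata, .data$n_products > 0)

  inventory <- if (!is.null(calls)) {
    species_inventory(calls)
  } else if ("identified_species" %in% names(df)) {
    species_inventory(tibble::tibble(sample_code = df$sample_code,
                                     status = "assigned",
                                     species = df$identified_species))
  } else {
    tibble::tibble(species = character(), n_products = integer())
  }
  idents <- if ("identity_pct" %in% names(df)) df$identity_pct else numeric()
  structure(list(
    strata = strata,
    species_inventory = inventory,
    identity_min = if (length(idents)) round_half_up(min(idents), 2) else NA_real_,
    identity_max = if (length(idents)) round_half_up(max(idents), 2) else NA_real_,
    n_sequences_processed = if ("processed_replicates" %in% names(df))
      sum(df$processed_replicates) else NA_integer_,
    n_unresolved = n_unres
  ), class = "survey_summary")
}

#' Extract one stratum's rate from a survey summary
#'
#' @param summary A `survey_summary`.
#' @param region,retail_type,category Stratum levels (`"all"` wildcards).
#' @param rounded Return the half-up integer-rounded rate.
#' @return The misdescription rate in percent for that stratum.
#' @export
stratum_rate <- function(summary, region = "all", retail_type = "all",
                         category = "all", rounded = FALSE) {
  stopifnot(inherits(summary, "survey_summary"))
  s <- summary$strata
  row <- s[s$region == region & s$retail_type == retail_type &
             s$category == category, ]
  if (nrow(row) != 1) {
    stop("no such stratum: ", region, "/", retail_type, "/", category,
         call. = FALSE)
  }
  if (rounded) row$rate_pct_rounded else row$rate_pct
}

#' Species inventory from assigned calls
#'
#' @param calls A data frame with `status` and `species` columns (only
#'   `assigned` rows contribute).
#' @return A tibble `species`, `n_products`, alphabetical by species.
#' @export
species_inventory <- function(calls) {
  assigned <- dplyr::filter(tibble::as_tibble(calls), .data$status == "assigned")
  assigned |>
    dplyr::count(.data$species, name = "n_products") |>
    dplyr::arrange(.data$species)
}

#' Summarize percent identities
#'
#' @param identities Non-empty numeric vector of percent identities.
#' @return A one-row tibble: `min`, `max`, `mean`, at 2-decimal reporting
#'   precision (half-up).
#' @export
identity_summary <- function(identities) {
  if (length(identities) == 0) stop("empty identity vector", call. = FALSE)
  tibble::tibble(min = round_half_up(min(identities), 2),
                 max = round_half_up(max(identities), 2),
                 mean = round_half_up(mean(identities), 2))
}

#' @export
print.survey_summary <- function(x, ...) {
  overall <- x$strata[x$strata$region == "all" & x$strata$retail_type == "all" &
                        x$strata$category == "all", ]
  cat("<survey_summary>\n")
  cat("  products: ", overall$n_products, " (", overall$n_misdescribed,
      " misdescribed, ", sprintf("%.1f", overall$rate_pct), "%)\n", sep = "")
  cat("  species identified: ", nrow(x$species_inventory), "\n", sep = "")
  if (!is.na(x$identity_min)) {
    cat("  identity range: ", x$identity_min, "-", x$identity_max, "\n", sep = "")
  }
  if (!is.na(x$n_sequences_processed)) {
    cat("  sequences processed: ", x$n_sequences_processed, "\n", sep = "")
  }
  invisible(x)
}

#' @rdname stratified_rates
#' @param x A `survey_summary`.
#' @param ... Unused.
#' @export
tidy.survey_summary <- function(x, ...) x$strata

#' @rdname stratified_rates
#' @export
glance.survey_summary <- function(x, ...) {
  overall <- x$strata[x$strata$region == "all" & x$strata$retail_type == "all" &
                        x$strata$category == "all", ]
  tibble::tibble(
    n_products = overall$n_products,
    n_misdescribed = overall$n_misdescribed,
    rate_pct = overall$rate_pct,
    n_species = nrow(x$species_inventory),
    identity_min = x$identity_min,
    identity_max = x$identity_max,
    n_sequences_processed = x$n_sequences_processed,
    n_unresolved = x$n_unresolved
  )
}

#' @rdname stratified_rates
#' @param object A `survey_summary`.
#' @export
autoplot.survey_summary <- function(object, ...) {
  df <- dplyr::filter(object$strata, .data$region != "all",
                      .data$retail_type == "all", .data$category != "all")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$rate_pct,
                                   fill = .data$region)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "product category", y = "misdescription rate (%)",
                  fill = "region") +
    ggplot2::theme_minimal()
}

#' Write / read a survey report
#'
#' `write_report()` serializes a `survey_summary` to JSON (lossless,
#' schema version 1) or TSV (one row per stratum); `read_report()` loads
#' a JSON report back into a `survey_summary`.
#'
#' @param summary A `survey_summary`.
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly (`write_report`); a `survey_summary`
#'   (`read_report`).
#' @export
write_report <- function(summary, path, format = c("json", "tsv")) {
  stopifnot(inherits(summary, "survey_summary"))
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(summary$strata, path)
  } else {
    payload <- list(
      schema = "coiauth_survey_report/1",
      strata = summary$strata,
      species_inventory = summary$species_inventory,
      identity_min = summary$identity_min,
      identity_max = summary$identity_max,
      n_sequences_processed = summary$n_sequences_processed,
      n_unresolved = summary$n_unresolved
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$schema, "coiauth_survey_report/1")) {
    stop("unrecognized report schema", call. = FALSE)
  }
  structure(list(
    strata = tibble::as_tibble(payload$strata),
    species_inventory = tibble::as_tibble(payload$species_inventory),
    identity_min = payload$identity_min,
    identity_max = payload$identity_max,
    n_sequences_processed = payload$n_sequences_processed,
    n_unresolved = payload$n_unresolved
  ), class = "survey_summary")
}

#' One-shot reproduction of the packaged survey
#'
#' Loads the fixture table(s), derives compliance verdicts from the
#' printed declared and identified species columns with the default name
#' rules, and computes the stratified summary. The computed verdicts can
#' be checked against the fixture's transcribed misdescription marking via
#' the returned `verdicts` tibble (column `misdescribed_fixture`).
#'
#' @param region Fixture region (default `"all"`).
#' @param rules,taxonomy Passed to [call_compliance()].
#' @return A list: `products` (the fixture), `verdicts` (compliance calls
#'   joined with the fixture marking), `summary` (a `survey_summary`).
#' @export
reproduce_survey <- function(region = "all", rules = default_name_rules(),
                             taxonomy = default_taxonomy()) {
  products <- load_fixture(region)
  calls <- tibble::tibble(sample_code = products$sample_code,
                          status = "assigned",
                          species = products$identified_species)
  verdicts <- call_compliance(products, calls, rules, taxonomy)
  verdicts <- dplyr::left_join(
    verdicts,
    dplyr::select(products, "sample_code",
                  misdescribed_fixture = "misdescribed"),
    by = "sample_code")
  summary <- stratified_rates(verdicts, products, calls)
  list(products = products, verdicts = verdicts, summary = summary)
}
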