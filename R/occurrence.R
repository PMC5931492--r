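#' Build an occurrence table from long-format records
#'
#' The canonical container in epidiv is a long tibble of occurrence records
#' with one row per (species, sample) pair and the sampling hierarchy carried
#' alongside: every sample (an epikarst drip, or a cave when caves are the
#' sampling unit) belongs to exactly one site, and every site to exactly one
#' region. Samples in which nothing was collected are retained as placeholder
#' rows with `species = NA` and `count = 0`, so that empty drips stay part of
#' the design (31% of drips in the Slovenian survey were empty).
#'
#' @param data A data frame with columns `species`, `sample`, `site`,
#'   `region` and optionally `count` (defaults to 1, i.e. incidence).
#'   Rows sharing a (species, sample) key are summed. A row with missing
#'   `species` (or `count = 0` for all its species) marks an empty sample.
#' @param sample_metadata Optional data frame of per-sample attributes
#'   (e.g. number of monthly collections), keyed by a `sample` column.
#'
#' @return A tibble of class `occurrence` with columns `species`, `sample`,
#'   `site`, `region`, `count`; empty samples appear as `NA`-species rows.
#'
#' @details Validation enforces: duplicate-free label sets, a functional
#'   sample -> (site, region) and site -> region mapping, and non-negative
#'   integer counts. A species listed but absent everywhere is kept with a
#'   warning and ignored by richness computations.
#'
#' @examples
#' occ <- occurrence(data.frame(
#'   species = c("sp1", "sp1", "sp2"),
#'   sample  = c("d1", "d2", "d1"),
#'   site    = "caveA", region = "reg1",
#'   count   = c(2, 1, 1)
#' ))
#' occ_matrix(occ)
#' @export
occurrence <- function(data, sample_metadata = NULL) {
  required <- c("species", "sample", "site", "region")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  if (!"count" %in% names(data)) data$count <- 1L

  if (any(is.na(data$sample) | is.na(data$site) | is.na(data$region))) {
    stop("sample, site and region labels must not be missing", call. = FALSE)
  }
  bad <- !is.na(data$count) & (data$count < 0 | data$count != round(data$count))
  if (any(bad)) {
    stop("counts must be non-negative integers; offending value(s): ",
         paste(utils::head(unique(data$count[bad]), 3), collapse = ", "),
         call. = FALSE)
  }
  data$count[is.na(data$count)] <- 0L
  data$count <- as.integer(round(data$count))
  # empty-sample placeholders: species NA (or "" from file IO)
  data$species[!is.na(data$species) & data$species == ""] <- NA_character_

  # hierarchy must be functional
  hier <- dplyr::distinct(data, .data$sample, .data$site, .data$region)
  dup_sample <- hier$sample[duplicated(hier$sample)]
  if (length(dup_sample) > 0) {
    stop("sample(s) assigned to more than one site/region: ",
         paste(unique(dup_sample), collapse = ", "), call. = FALSE)
  }
  site_map <- dplyr::distinct(hier, .data$site, .data$region)
  dup_site <- site_map$site[duplicated(site_map$site)]
  if (length(dup_site) > 0) {
    stop("site(s) assigned to more than one region: ",
         paste(unique(dup_site), collapse = ", "), call. = FALSE)
  }

  # collapse duplicate (species, sample) keys; keep one placeholder row for
  # samples with no positive record
  records <- data |>
    dplyr::filter(!is.na(.data$species)) |>
    dplyr::group_by(.data$species, .data$sample, .data$site, .data$region) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")

  ghost <- records |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop") |>
    dplyr::filter(.data$total == 0)
  if (nrow(ghost) > 0) {
    warning("species never observed (all-zero counts), excluded from richness: ",
            paste(ghost$species, collapse = ", "), call. = FALSE)
  }

  occupied <- unique(records$sample[records$count > 0])
  empties <- hier |>
    dplyr::filter(!.data$sample %in% occupied) |>
    dplyr::mutate(species = NA_character_, count = 0L)
  out <- dplyr::bind_rows(
    dplyr::filter(records, .data$count > 0 |
                    .data$species %in% ghost$species),
    empties
  ) |>
    dplyr::select("species", "sample", "site", "region", "count") |>
    dplyr::arrange(.data$region, .data$site, .data$sample, .data$species)

  if (!is.null(sample_metadata)) {
    stopifnot("sample" %in% names(sample_metadata))
    attr(out, "sample_metadata") <- tibble::as_tibble(sample_metadata)
  }
  class(out) <- c("occurrence", class(tibble::tibble()))
  out
}

#' @export
print.occurrence <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<occurrence> %d species x %d samples (%d empty) | %d sites, %d regions, %d individuals\n",
    g$n_species, g$n_samples, g$n_empty_samples, g$n_sites, g$n_regions,
    g$n_individuals
  ))
  NextMethod()
}

#' One-row summary of an occurrence table
#'
#' @param x An [occurrence()] object.
#' @param ... Unused.
#' @return A one-row tibble: `n_species`, `n_samples`, `n_empty_samples`,
#'   `n_sites`, `n_regions`, `n_individuals`.
#' @export
glance.occurrence <- function(x, ...) {
  hier <- sample_hierarchy(x)
  pos <- dplyr::filter(x, !is.na(.data$species), .data$count > 0)
  tibble::tibble(
    n_species = dplyr::n_distinct(pos$species),
    n_samples = nrow(hier),
    n_empty_samples = nrow(hier) - dplyr::n_distinct(pos$sample),
    n_sites = dplyr::n_distinct(hier$site),
    n_regions = dplyr::n_distinct(hier$region),
    n_individuals = sum(pos$count)
  )
}

#' Sampling hierarchy of an occurrence table
#'
#' @param x An [occurrence()] object.
#' @return A tibble with one row per sample: `sample`, `site`, `region`.
#' @export
sample_hierarchy <- function(x) {
  dplyr::distinct(tibble::as_tibble(x), .data$sample, .data$site, .data$region) |>
    dplyr::arrange(.data$region, .data$site, .data$sample)
}

#' Species-by-unit matrix at a chosen hierarchy level
#'
#' Pools member samples by summation, so a cave's column is the sum of its
#' drips' columns and a region's the sum of its caves'. Empty units are kept
#' as all-zero columns.
#'
#' @param x An [occurrence()] object.
#' @param level `"sample"`, `"site"` or `"region"`.
#' @param incidence If `TRUE`, reduce the pooled counts to presence/absence.
#' @return An integer matrix, species in rows, units in columns.
#' @export
occ_matrix <- function(x, level = c("sample", "site", "region"),
                       incidence = FALSE) {
  level <- match.arg(level)
  hier <- sample_hierarchy(x)
  units <- unique(hier[[level]])
  pos <- dplyr::filter(tibble::as_tibble(x), !is.na(.data$species))
  species <- sort(unique(pos$species))
  m <- matrix(0L, nrow = length(species), ncol = length(units),
              dimnames = list(species, units))
  if (nrow(pos) > 0) {
    agg <- pos |>
      dplyr::group_by(.data$species, unit = .data[[level]]) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop")
    m[cbind(agg$species, agg$unit)] <- as.integer(agg$count)
  }
  if (incidence) m <- (m > 0) + 0L
  m
}

#' Pool an occurrence table to a coarser hierarchy level
#'
#' Aggregates counts of member samples; the pooled units become the samples
#' of the returned object (sites pooled to regions keep `site == region`).
#' Total counts are conserved exactly.
#'
#' @param x An [occurrence()] object.
#' @param level `"site"` or `"region"`.
#' @return An [occurrence()] object with one sample per pooled unit.
#' @examples
#' caves <- load_fixture("cave_incidence")
#' glance(pool(caves, "region"))
#' @export
pool <- function(x, level = c("site", "region")) {
  level <- match.arg(level)
  df <- tibble::as_tibble(x)
  if (level == "site") {
    df <- dplyr::mutate(df, sample = .data$site)
  } else {
    df <- dplyr::mutate(df, sample = .data$region, site = .data$region)
  }
  occurrence(df)
}

#' Per-unit species richness
#'
#' @param x An [occurrence()] object.
#' @param level `"sample"`, `"site"` or `"region"`.
#' @return A tibble with one row per unit: `unit`, `site`, `region`,
#'   `richness`, `n_individuals`.
#' @examples
#' unit_richness(load_fixture("cave_incidence"), "sample")
#' @export
unit_richness <- function(x, level = c("sample", "site", "region")) {
  level <- match.arg(level)
  m <- occ_matrix(x, level)
  hier <- sample_hierarchy(x)
  key <- dplyr::distinct(hier, unit = .data[[level]], .data$region)
  if (level == "sample") key$site <- hier$site[match(key$unit, hier$sample)]
  if (level == "site") key$site <- key$unit
  if (level == "region") key$site <- key$unit
  tibble::tibble(
    unit = colnames(m),
    richness = unname(colSums(m > 0)),
    n_individuals = unname(colSums(m))
  ) |>
    dplyr::left_join(key, by = "unit") |>
    dplyr::select("unit", "site", "region", "richness", "n_individuals")
}

#' Read an occurrence table from a long-format delimited file
#'
#' Expects columns `species,sample,site,region[,count]`; the delimiter (comma
#' or tab) is auto-detected from the header line. Empty `species` fields mark
#' empty samples. Rows with identical (species, sample) keys are summed.
#'
#' @param path Path to a delimited text file.
#' @return An [occurrence()] object.
#' @export
read_occurrence <- function(path) {
  delim <- detect_delim(path)
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
  if ("count" %in% names(df)) {
    count_num <- suppressWarnings(as.numeric(df$count))
    if (any(is.na(count_num) & !is.na(df$count) & df$count != "")) {
      stop("non-numeric count values in ", path, call. = FALSE)
    }
    df$count <- count_num
  }
  occurrence(df)
}

#' Read an occurrence table from a species-by-sample matrix file
#'
#' The matrix file has species in rows, sample ids as the header row; the
#' companion hierarchy file has columns `sample,site,region`. This mirrors
#' the layout in which cave-occupancy tables are usually printed.
#'
#' @param path Matrix file (first column species labels).
#' @param hierarchy_path Hierarchy file.
#' @return An [occurrence()] object.
#' @export
read_occurrence_matrix <- function(path, hierarchy_path) {
  m <- readr::read_delim(path, delim = detect_delim(path),
                         show_col_types = FALSE)
  h <- readr::read_delim(hierarchy_path, delim = detect_delim(hierarchy_path),
                         show_col_types = FALSE)
  stopifnot(all(c("sample", "site", "region") %in% names(h)))
  names(m)[1] <- "species"
  long <- tidyr::pivot_longer(m, -"species", names_to = "sample",
                              values_to = "count") |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0))
  unknown <- setdiff(long$sample, h$sample)
  if (length(unknown) > 0) {
    stop("sample(s) missing from hierarchy file: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  long <- dplyr::left_join(long, h, by = "sample") |>
    dplyr::filter(.data$count > 0)
  # samples absent from `long` (all-zero columns) re-enter as empties
  empties <- dplyr::filter(h, !.data$sample %in% long$sample) |>
    dplyr::mutate(species = NA_character_, count = 0)
  occurrence(dplyr::bind_rows(long, empties))
}

#' Write an occurrence table as long-format delimited text
#'
#' Empty samples are written as rows with a blank species field and count 0,
#' so that `read_occurrence(write_occurrence(x, p))` round-trips exactly.
#'
#' @param x An [occurrence()] object.
#' @param path Output path.
#' @param delim Field delimiter, default comma.
#' @return `path`, invisibly.
#' @export
write_occurrence <- function(x, path, delim = ",") {
  df <- tibble::as_tibble(x) |>
    dplyr::mutate(species = dplyr::coalesce(.data$species, ""))
  readr::write_delim(df, path, delim = delim, na = "")
  invisible(path)
}

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}
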