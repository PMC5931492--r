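#' Load a packaged survey fixture
#'
#' The package ships the published Slovenian epikarst copepod survey tables
#' as plain-text fixtures (see the extdata `MANIFEST.md` for provenance and
#' for the documented internal inconsistencies of the printed tables, which
#' are kept as printed, never silently reconciled).
#'
#' @param name One of:
#'   * `"cave_incidence"` — species x cave occupancy (counts = number of
#'     drips occupied), 30 species, 13 caves, 3 regions; an [occurrence()]
#'     object with caves as samples and sites.
#'   * `"snezna_drips"` — drip-level reconstruction for Snezna jama
#'     (5 drips, 2 empty, 3 with both species); an [occurrence()] object.
#'     Composition is forced by the published tables, not printed per drip.
#'   * `"jpbz_drips"` — drip-level reconstruction for Jama pod Babjim zobom
#'     (5 drips: 1 empty, two 1-species, two 3-species); an [occurrence()]
#'     object; trusts the drip-richness histogram where it conflicts with
#'     the occupancy table.
#'   * `"drip_distribution"` — per-cave histogram of per-drip richness;
#'     a tibble `cave, region, n_species, n_drips`.
#'   * `"cave_summary"` — per-cave drip summary (min/max/mean per-drip
#'     richness, cave total, within-cave Sorensen and % turnover);
#'     a tibble.
#'
#' @return An [occurrence()] object or a tibble, depending on `name`.
#' @examples
#' glance(load_fixture("cave_incidence"))
#' @export
load_fixture <- function(name = c("cave_incidence", "snezna_drips",
                                  "jpbz_drips", "drip_distribution",
                                  "cave_summary")) {
  name <- match.arg(name)
  file <- switch(name,
    cave_incidence    = "cave_occupancy_long.csv",
    snezna_drips      = "snezna_drips_reconstructed.csv",
    jpbz_drips        = "jpbz_drips_reconstructed.csv",
    drip_distribution = "drip_richness_distribution.csv",
    cave_summary      = "cave_drip_summary.csv"
  )
  path <- system.file("extdata", file, package = "epidiv", mustWork = TRUE)
  if (name %in% c("cave_incidence", "snezna_drips", "jpbz_drips")) {
    read_occurrence(path)
  } else {
    readr::read_csv(path, show_col_types = FALSE)
  }
}
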