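# Packaged fixtures

All files are plain-text CSV encodings of the published survey tables for the
Slovenian epikarst copepod study (30 stygobiotic species, 81 drips, 13 caves,
3 karst regions). Cave and species names are ASCII-transliterated
(Crna = Črna, Snezna = Snežna, Skocjanske = Škocjanske, Zupanova = Županova,
Poloska = Pološka, Zadlaska = Zadlaška).

## cave_occupancy_long.csv
Long-format species x cave occupancy: `count` is the number of drips in that
cave in which the species was found. Caves act both as samples and as sites,
grouped into the Dinaric / Alpine / Isolated regions. Every per-species drip
total and every per-cave species total reproduces the published row/column
totals. Known internal inconsistency kept as printed: *Bryocamptus* n.sp. 2
has three positive cells (Poloska 3, Snezna 3, Zadlaska 1; drip total 7) while
the published "N caves" column says 2 — the Zadlaska cell is required by that
cave's published species total (3) and occurrence count (4). Pooling this
table to regions yields richness 25 (Dinaric), 5 (Alpine), 5 (Isolated);
the published regional table prints 6 for Alpine and 4 for Isolated, an
inconsistency that is documented, not reconciled.

## drip_richness_distribution.csv
Per-cave histogram of per-drip species richness (`n_drips` drips with exactly
`n_species` species). Column sums reproduce the published totals:
81 drips, 25 empty, 11 drips with >= 5 species.

## snezna_drips_reconstructed.csv, jpbz_drips_reconstructed.csv
SYNTHETIC drip-level reconstructions: per-drip composition was not published;
these are the unique (Snezna) resp. simplest (Jama pod Babjim zobom)
assemblage sets consistent with the per-cave richness histogram and the
species occupancy table. Snezna: 5 drips, 2 empty, 3 containing both of the
cave's species (forced jointly by both tables). Jama pod Babjim zobom: the
histogram implies 8 occurrences over drips of richness 0/1/1/3/3 while the
occupancy table implies only 6; the reconstruction trusts the histogram
(1 empty drip, two 1-species drips, two 3-species drips sharing the same
3 species), which reproduces the published within-cave Sorensen value 0.44
with 0% turnover. Counts are presence (1) only.

## cave_drip_summary.csv
Per-cave drip-richness summary as published: min/max/mean per-drip richness
(`min_sd`, `max_sd`, `mean_sd`), total cave richness (`total_s`), within-cave
multiple-site Sorensen dissimilarity (`beta_sor`) and percent of it due to
turnover (`pct_turnover`; blank where dissimilarity is 0). Mean values are
as printed even where inconsistent with the histogram (e.g. Snezna 0.8
printed vs 1.2 implied; Huda luknja 0.33 = 4 occurrences / 12 drips,
empty drips included).
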