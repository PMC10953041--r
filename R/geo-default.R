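# Default geographic model: 14 areas, four slices bounded at 358.9, 201.3, 66
# and 23 Ma (Carboniferous-Triassic / Jurassic-Cretaceous / Paleogene /
# Neogene-present). Adjacencies are a coarse reading of standard paleogeographic
# reconstructions (Pangea assembly, Gondwana/Laurasia breakup, Cenozoic plate
# positions); users with different paleogeographic opinions should supply their
# own matrices via geo_model() or a YAML config.

.cycad_area_codes <- c("WP", "EP", "WN", "EN", "CA", "WI", "SA",
                       "AF", "MA", "IN", "WA", "AU", "GR", "AN")

.cycad_area_names <- c(
  "West Palearctic", "East Palearctic", "West Nearctic", "East Nearctic",
  "Central America", "Caribbean Islands", "South America", "Africa",
  "Madagascar", "India", "Indonesia and Wallacea", "Australasia",
  "Greenland", "Antarctica")

.cycad_high_latitude <- c("WP", "EP", "WN", "EN", "GR", "AN")

.adj_from_pairs <- function(codes, pairs) {
  A <- length(codes)
  m <- diag(1L, A)
  dimnames(m) <- list(codes, codes)
  for (p in pairs) {
    i <- match(p[1], codes); j <- match(p[2], codes)
    m[i, j] <- m[j, i] <- 1L
  }
  m
}

#' Default cycad geographic model (14 areas, 4 time slices)
#'
#' Fourteen areas (West/East Palearctic, West/East Nearctic, Central America,
#' Caribbean, South America, Africa, Madagascar, India, Indonesia-Wallacea,
#' Australasia, Greenland, Antarctica) with connectivity matrices for four
#' geological time slices: 358.9-201.3 Ma (Pangea), 201.3-66 Ma
#' (Gondwana/Laurasia), 66-23 Ma (Paleogene) and 23-0 Ma (Neogene-present).
#'
#' @param max_range_size largest allowed range size (default 5).
#' @param high_latitude character vector of area codes classed as
#'   high-latitude for event summaries (default WP, EP, WN, EN, GR, AN).
#' @return a `geo_model`.
#' @export
default_cycad_geo <- function(max_range_size = 5L,
                              high_latitude = .cycad_high_latitude) {
  codes <- .cycad_area_codes
  areas <- tibble(
    code = codes,
    name = .cycad_area_names,
    latitude_class = ifelse(codes %in% high_latitude, "high", "low"))

  pangea <- .adj_from_pairs(codes, list(
    c("WP", "EP"), c("WP", "GR"), c("WP", "EN"), c("WP", "AF"),
    c("EP", "WA"), c("GR", "EN"), c("WN", "EN"), c("WN", "CA"),
    c("EN", "CA"), c("EN", "AF"), c("CA", "SA"), c("SA", "AF"),
    c("SA", "AN"), c("AF", "MA"), c("AF", "AN"), c("MA", "IN"),
    c("IN", "AN"), c("AU", "AN"), c("MA", "AN"), c("WA", "IN")))

  mesozoic <- .adj_from_pairs(codes, list(
    c("WP", "EP"), c("WP", "GR"), c("GR", "EN"), c("WN", "EN"),
    c("WN", "EP"), c("WN", "CA"), c("EN", "CA"), c("CA", "WI"),
    c("WI", "SA"), c("SA", "AF"), c("SA", "AN"), c("AF", "MA"),
    c("MA", "IN"), c("IN", "AN"), c("AU", "AN"), c("EP", "WA")))

  paleogene <- .adj_from_pairs(codes, list(
    c("WP", "EP"), c("WP", "GR"), c("WP", "AF"), c("GR", "EN"),
    c("WN", "EN"), c("WN", "EP"), c("WN", "CA"), c("EN", "CA"),
    c("CA", "WI"), c("WI", "SA"), c("SA", "AN"), c("AF", "MA"),
    c("IN", "EP"), c("IN", "WA"), c("EP", "WA"), c("AU", "AN")))

  neogene <- .adj_from_pairs(codes, list(
    c("WP", "EP"), c("WP", "AF"), c("WP", "GR"), c("GR", "EN"),
    c("WN", "EN"), c("WN", "EP"), c("WN", "CA"), c("EN", "CA"),
    c("CA", "WI"), c("CA", "SA"), c("WI", "SA"), c("AF", "MA"),
    c("IN", "EP"), c("IN", "WA"), c("EP", "WA"), c("WA", "AU")))

  geo_model(
    areas = areas,
    slices = list(
      list(older_bound = 358.9, younger_bound = 201.3, adjacency = pangea),
      list(older_bound = 201.3, younger_bound = 66,    adjacency = mesozoic),
      list(older_bound = 66,    younger_bound = 23,    adjacency = paleogene),
      list(older_bound = 23,    younger_bound = 0,     adjacency = neogene)),
    max_range_size = max_range_size)
}
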