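# File formats: Newick/NEXUS trees (via ape), Lagrange/PHYLIP-style range
# matrices with '?' fossil coding, YAML geographic-model configs, TSV latitude
# tables, TSV/JSON outputs.

#' Read a dated tree (Newick or NEXUS)
#'
#' Node ages are derived from branch lengths ([tree_ages()]); tips within
#' `extant_tol` of the present are extant, earlier-ending tips are fossils.
#'
#' @param path file path; format auto-detected (`#NEXUS` header).
#' @param extant_tol tolerance (Myr) for treating a tip as extant.
#' @return a `phylo` (validated binary, non-negative branch lengths).
#' @export
read_dated_tree <- function(path, extant_tol = 0.001) {
  first <- toupper(trimws(readLines(path, n = 1, warn = FALSE)))
  tr <- if (startsWith(first, "#NEXUS")) ape::read.nexus(path)
        else ape::read.tree(path)
  if (inherits(tr, "multiPhylo")) tr <- tr[[1]]
  if (is.null(tr)) abort(sprintf("could not parse tree file '%s'", path))
  .validate_tree(tr)
  invisible(tree_ages(tr, extant_tol))
  tr
}

#' Write a dated tree
#' @param tree a `phylo`.
#' @param path output path; `format` `"newick"` or `"nexus"`.
#' @param format output dialect.
#' @export
write_dated_tree <- function(tree, path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  if (format == "newick") ape::write.tree(tree, path)
  else ape::write.nexus(tree, file = path)
  invisible(path)
}

#' Read a Lagrange-style range matrix
#'
#' Header line `ntaxa nareas`, then one line per taxon: label, whitespace, a
#' binary string over the areas with `?` allowed. Any `?` marks the taxon as
#' ambiguously coded (presences are the `1` positions, absences unknown).
#'
#' @param path file path.
#' @param geo a `geo_model` (defines the area count and order).
#' @return tibble with `label`, `mask`, `ambiguous`.
#' @export
read_ranges <- function(path, geo) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) < 2) abort("range file: malformed header (want 'ntaxa nareas')")
  ntaxa <- as.integer(hdr[1]); nareas <- as.integer(hdr[2])
  A <- nrow(geo$areas)
  if (nareas != A)
    abort(sprintf("range file declares %d areas but the model has %d", nareas, A))
  body <- lines[-1]
  if (length(body) != ntaxa)
    abort(sprintf("range file declares %d taxa but has %d rows", ntaxa, length(body)))
  out <- lapply(seq_along(body), function(li) {
    parts <- strsplit(trimws(body[li]), "\\s+")[[1]]
    if (length(parts) < 2)
      abort(sprintf("range file line %d: want 'label binary-string'", li + 1L))
    lab <- paste(parts[-length(parts)], collapse = " ")
    str <- parts[length(parts)]
    ch <- strsplit(str, "")[[1]]
    if (length(ch) != A)
      abort(sprintf("range file line %d ('%s'): string width %d, expected %d",
                    li + 1L, lab, length(ch), A))
    if (!all(ch %in% c("0", "1", "?")))
      abort(sprintf("range file line %d: characters must be 0, 1 or ?", li + 1L))
    mask <- range_mask(which(ch == "1"))
    if (mask == 0L)
      abort(sprintf("range file line %d ('%s'): no presences coded", li + 1L, lab))
    tibble(label = lab, mask = mask, ambiguous = any(ch == "?"))
  })
  bind_rows(out)
}

#' Write a Lagrange-style range matrix
#' @param observations tibble with `label`, `mask`, `ambiguous`.
#' @param geo a `geo_model`.
#' @param path output path.
#' @export
write_ranges <- function(observations, geo, path) {
  A <- nrow(geo$areas)
  rows <- vapply(seq_len(nrow(observations)), function(i) {
    m <- observations$mask[i]
    ch <- ifelse(bitwAnd(m, .bit(seq_len(A))) != 0L, "1",
                 if (isTRUE(observations$ambiguous[i])) "?" else "0")
    paste0(observations$label[i], "\t", paste(ch, collapse = ""))
  }, character(1))
  writeLines(c(paste(nrow(observations), A), rows), path)
  invisible(path)
}

#' Read a geographic-model config (YAML)
#'
#' Schema: `areas:` list of `{code, name, latitude_class}`; `slices:` list of
#' `{older_bound, younger_bound, adjacency}` with adjacency as a list of 0/1
#' rows (oldest slice first); `max_range_size:` integer.
#'
#' @param path YAML file path.
#' @return a `geo_model`.
#' @export
read_geo_model <- function(path) {
  cfg <- yaml::read_yaml(path)
  areas <- bind_rows(lapply(cfg$areas, as_tibble))
  slices <- lapply(cfg$slices, function(s) {
    adj <- do.call(rbind, lapply(s$adjacency, as.integer))
    list(older_bound = as.numeric(s$older_bound),
         younger_bound = as.numeric(s$younger_bound), adjacency = adj)
  })
  geo_model(areas, slices, max_range_size = cfg$max_range_size %||% 5L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a geographic-model config (YAML)
#' @param geo a `geo_model`.
#' @param path output path.
#' @export
write_geo_model <- function(geo, path) {
  cfg <- list(
    areas = lapply(seq_len(nrow(geo$areas)), function(i)
      list(code = geo$areas$code[i], name = geo$areas$name[i],
           latitude_class = geo$areas$latitude_class[i])),
    slices = lapply(geo$slices, function(s)
      list(older_bound = s$older_bound, younger_bound = s$younger_bound,
           adjacency = lapply(seq_len(nrow(s$adjacency)),
                              function(r) as.integer(s$adjacency[r, ])))),
    max_range_size = geo$max_range_size)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a latitude table (TSV: label, latitude_degrees, age_Ma)
#' @param path file path.
#' @return tibble with `label`, `latitude`, `age`.
#' @export
read_latitudes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  lat_col <- intersect(c("latitude", "latitude_degrees"), names(df))[1]
  age_col <- intersect(c("age", "age_ma"), names(df))[1]
  if (is.na(lat_col) || !"label" %in% names(df))
    abort("latitude table needs columns label, latitude[_degrees][, age[_Ma]]")
  tibble(label = df$label, latitude = as.numeric(df[[lat_col]]),
         age = if (!is.na(age_col)) as.numeric(df[[age_col]]) else 0)
}

#' Write a latitude table
#' @param latitudes tibble with `label`, `latitude` and optionally `age`.
#' @param path output path.
#' @export
write_latitudes <- function(latitudes, path) {
  df <- data.frame(label = latitudes$label,
                   latitude_degrees = latitudes$latitude,
                   age_Ma = latitudes$age %||% 0)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
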