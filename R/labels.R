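#' @useDynLib rinnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# The 18 Leontis-Westhof pair geometries plus the two backbone pseudo-geometries.
# A geometry string is x YZ with x in {c,t} (glycosidic orientation) and
# Y, Z in {W,H,S} (interacting edge of the 5'-side and 3'-side nucleotide).
LW_GEOMETRIES <- as.vector(outer(
  c("c", "t"),
  as.vector(outer(c("W", "H", "S"), c("W", "H", "S"), paste0)),
  paste0
))
BACKBONE_GEOMETRIES <- c("b53", "b35")
ALL_GEOMETRIES <- c(LW_GEOMETRIES, BACKBONE_GEOMETRIES)
RANGE_FLAGS <- c("local", "long_range")

#' Construct edge labels
#'
#' An edge label (the graph's "color") is an interaction geometry plus a range
#' flag, encoded as a single string `"<geometry>/<range>"`, e.g. `"cWH/local"`
#' or `"tSS/long_range"`. Geometries are the 18 Leontis-Westhof pair codes
#' (`{c,t} x {W,H,S}^2`) or the backbone codes `b53`/`b35`; backbone labels are
#' always local.
#'
#' @param geometry character vector of geometry codes.
#' @param range character vector, `"local"` or `"long_range"` (recycled).
#' @return character vector of label strings.
#' @examples
#' edge_label("cWH")
#' edge_label("tSS", "long_range")
#' @export
edge_label <- function(geometry, range = "local") {
  range <- rep_len(range, length(geometry))
  bad <- !(geometry %in% ALL_GEOMETRIES)
  if (any(bad)) {
    abort(paste0("invalid geometry code(s): ",
                 paste(unique(geometry[bad]), collapse = ", ")),
          class = "rinnet_bad_label")
  }
  if (any(!(range %in% RANGE_FLAGS))) {
    abort("range must be 'local' or 'long_range'", class = "rinnet_bad_label")
  }
  if (any(geometry %in% BACKBONE_GEOMETRIES & range != "local")) {
    abort("backbone labels are always local", class = "rinnet_bad_label")
  }
  paste0(geometry, "/", range)
}

#' @rdname edge_label
#' @param label character vector of label strings.
#' @export
label_geometry <- function(label) sub("/.*$", "", label)

#' @rdname edge_label
#' @export
label_range <- function(label) sub("^.*/", "", label)

#' @rdname edge_label
#' @export
is_backbone_label <- function(label) label_geometry(label) %in% BACKBONE_GEOMETRIES

#' @rdname edge_label
#' @export
is_pair_label <- function(label) label_geometry(label) %in% LW_GEOMETRIES

#' @rdname edge_label
#' @export
is_canonical_label <- function(label) label_geometry(label) == "cWW"

check_label <- function(label) {
  geom <- label_geometry(label)
  rng <- label_range(label)
  bad <- !(geom %in% ALL_GEOMETRIES) | !(rng %in% RANGE_FLAGS) |
    (geom %in% BACKBONE_GEOMETRIES & rng != "local")
  if (any(bad)) {
    abort(paste0("invalid edge label(s): ",
                 paste(unique(label[bad]), collapse = ", ")),
          class = "rinnet_bad_label")
  }
  invisible(label)
}

#' Reverse-direction label bijection
#'
#' Every interaction between nucleotides a and b is stored as two directed
#' edges `(a, b, L)` and `(b, a, iota(L))`. `iota` swaps the two interacting
#' edges of a pair geometry (`xYZ -> xZY`) and exchanges the backbone
#' directions (`b53 <-> b35`); symmetric geometries (`xYY`) are fixed points.
#' The range flag is preserved. `iota` is an involution.
#'
#' @param label character vector of edge labels.
#' @return character vector of reversed labels.
#' @examples
#' iota(edge_label("cWH"))                 # "cHW/local"
#' iota(edge_label("tSS", "long_range"))   # unchanged
#' iota(edge_label("b53"))                 # "b35/local"
#' @export
iota <- function(label) {
  check_label(label)
  geom <- label_geometry(label)
  rng <- label_range(label)
  rev_geom <- ifelse(
    geom == "b53", "b35",
    ifelse(geom == "b35", "b53",
           paste0(substr(geom, 1, 1), substr(geom, 3, 3), substr(geom, 2, 2)))
  )
  paste0(rev_geom, "/", rng)
}

all_edge_labels <- function() {
  c(edge_label(LW_GEOMETRIES, "local"),
    edge_label(LW_GEOMETRIES, "long_range"),
    edge_label(BACKBONE_GEOMETRIES, "local"))
}
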