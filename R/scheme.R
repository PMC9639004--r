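#' Reaction kinds recognised in a migration/hydrolysis scheme
#'
#' Migration reactions move an acetyl group between hydroxyls and conserve
#' the acetyl count; hydrolysis reactions lose one acetyl to solvent.
#' Cross-unit migrations traverse the glycosidic linkage (nine-membered
#' orthoester intermediate), adjacent ones stay on the same ring
#' (five-membered intermediate).
#'
#' @return Character vector of the four valid reaction kinds.
#' @export
reaction_kinds <- function() {
  c("migration_adjacent", "migration_crossunit",
    "hydrolysis_secondary", "hydrolysis_primary")
}

#' Construct a migration/hydrolysis reaction scheme
#'
#' A scheme is a declarative description of a first-order reaction network
#' over acetylation states of an oligosaccharide: a set of species (each a
#' set of occupied acetyl positions), a set of directed reactions labelled
#' with rate-constant symbols, and the ordered list of free rate symbols.
#' Several reactions may share one symbol (tied constants, e.g. hydrolysis
#' from chemically equivalent secondary positions).
#'
#' @param name Scheme name.
#' @param species Named list: species id -> character vector of acetyl
#'   position tags, each `"unit:site"` (e.g. `"mid:O2"`, `"red:O6"`).  The
#'   fully deacetylated species has an empty vector.
#' @param reactions Data frame with columns `reactant`, `product`,
#'   `rate_symbol`, `kind` (one of [reaction_kinds()]) and optionally
#'   `ph_sensitive` (logical, default `TRUE`: the constant is scaled with
#'   the hydroxide concentration, see [ph_scale_factor()]).
#' @param rate_symbols Ordered character vector of free rate-constant
#'   symbols; defaults to the symbols in order of first appearance.
#'
#' @return An object of class `migkin_scheme`.
#' @seealso [build_xylan_scheme()], [build_glucan_scheme()],
#'   [validate_scheme()]
#' @export
new_scheme <- function(name, species, reactions, rate_symbols = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  stopifnot(is.list(species), !is.null(names(species)))
  species <- lapply(species, as.character)
  rx <- as.data.frame(reactions, stringsAsFactors = FALSE)
  needed <- c("reactant", "product", "rate_symbol", "kind")
  missing_cols <- setdiff(needed, names(rx))
  if (length(missing_cols)) {
    stop("reactions is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(rx$ph_sensitive)) rx$ph_sensitive <- TRUE
  rx <- rx[, c(needed, "ph_sensitive")]
  if (is.null(rate_symbols)) rate_symbols <- unique(rx$rate_symbol)
  structure(
    list(name = name, species = species, reactions = rx,
         rate_symbols = as.character(rate_symbols)),
    class = "migkin_scheme"
  )
}

#' @export
print.migkin_scheme <- function(x, ...) {
  cat("<migkin_scheme> ", x$name, "\n", sep = "")
  cat("  species (", length(x$species), "): ",
      paste(sprintf("%s[%d]", names(x$species), acetyl_counts(x)),
            collapse = " "), "\n", sep = "")
  cat("  reactions (", nrow(x$reactions), "):\n", sep = "")
  for (i in seq_len(nrow(x$reactions))) {
    r <- x$reactions[i, ]
    cat(sprintf("    %s -> %s  (%s, %s)\n",
                r$reactant, r$product, r$rate_symbol, r$kind))
  }
  cat("  free rate symbols: ", paste(x$rate_symbols, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Acetyl count of every species in a scheme
#'
#' @param scheme A `migkin_scheme`.
#' @return Named integer vector of acetyl counts.
#' @export
acetyl_counts <- function(scheme) {
  vapply(scheme$species, length, integer(1))
}

#' Xylan model trisaccharide scheme
#'
#' Migration and hydrolysis network of a beta-(1->4)-linked
#' xylotrisaccharide acetylated on the middle unit.  Species: `1a`
#' (2,3-di-O-acetyl), `1b` (2-O-acetyl), `1c` (3-O-acetyl), `1d`
#' (deacetylated).  The O2 and O3 acetyls interconvert by fast adjacent
#' migration (`k2` forward O2 -> O3, `k-2` reverse); hydrolysis from the
#' diacetylated species proceeds through two parallel channels sharing
#' `k1` (sterically hindered by the neighbouring acetyl), and hydrolysis
#' from either monoacetylated species shares `k3`.  Xylose has no primary
#' O6, and no migration between the saccharide units is included.
#'
#' @return A `migkin_scheme` with 4 species and 4 free rate symbols.
#' @seealso [xylan_rate_constants()] for the fitted constants at pH 8.
#' @export
build_xylan_scheme <- function() {
  species <- list(
    "1a" = c("mid:O2", "mid:O3"),
    "1b" = "mid:O2",
    "1c" = "mid:O3",
    "1d" = character(0)
  )
  reactions <- data.frame(
    reactant    = c("1a", "1a", "1b", "1c", "1b", "1c"),
    product     = c("1b", "1c", "1c", "1b", "1d", "1d"),
    rate_symbol = c("k1", "k1", "k2", "k-2", "k3", "k3"),
    kind = c("hydrolysis_secondary", "hydrolysis_secondary",
             "migration_adjacent", "migration_adjacent",
             "hydrolysis_secondary", "hydrolysis_secondary"),
    stringsAsFactors = FALSE
  )
  new_scheme("xylan", species, reactions,
             rate_symbols = c("k1", "k2", "k-2", "k3"))
}

#' Glucan model trisaccharide scheme
#'
#' Migration and hydrolysis network of a beta-(1->4)-linked glucan
#' trisaccharide.  Unlike xylose, glucose carries a primary O6, so acetyl
#' groups migrate irreversibly across the glycosidic bond from the middle
#' unit's O2 to the reducing-end O6 (`k1` from the diacetylated `2a`,
#' `k3` from the monoacetylated `2e`; the two could not be merged into a
#' single cross-unit constant).  Species: `2a` (mid O2+O3), `2b` (mid O3 +
#' red O6), `2c` (mid O2 + red O6), `2d` (mid O3), `2e` (mid O2), `2f`
#' (red O6), `2g` (deacetylated).  Adjacent O2 <-> O3 migration shares
#' `k2`/`k-2` between the di- and mono-acetylated pairs; hydrolysis shares
#' `k_hydr_sec` per secondary acetyl and `k_hydr_prim` per primary acetyl.
#'
#' @return A `migkin_scheme` with 7 species and 6 free rate symbols.
#' @seealso [glucan_rate_constants()] for the fitted constants at pH 8.
#' @export
build_glucan_scheme <- function() {
  species <- list(
    "2a" = c("mid:O2", "mid:O3"),
    "2b" = c("mid:O3", "red:O6"),
    "2c" = c("mid:O2", "red:O6"),
    "2d" = "mid:O3",
    "2e" = "mid:O2",
    "2f" = "red:O6",
    "2g" = character(0)
  )
  reactions <- data.frame(
    reactant = c("2a",
                 "2b", "2c", "2d", "2e",
                 "2e",
                 "2a", "2a", "2b", "2c", "2d", "2e",
                 "2b", "2c", "2f"),
    product  = c("2b",
                 "2c", "2b", "2e", "2d",
                 "2f",
                 "2d", "2e", "2f", "2f", "2g", "2g",
                 "2d", "2e", "2g"),
    rate_symbol = c("k1",
                    "k-2", "k2", "k-2", "k2",
                    "k3",
                    rep("k_hydr_sec", 6),
                    rep("k_hydr_prim", 3)),
    kind = c("migration_crossunit",
             rep("migration_adjacent", 4),
             "migration_crossunit",
             rep("hydrolysis_secondary", 6),
             rep("hydrolysis_primary", 3)),
    stringsAsFactors = FALSE
  )
  new_scheme("glucan", species, reactions,
             rate_symbols = c("k1", "k2", "k-2", "k3",
                              "k_hydr_prim", "k_hydr_sec"))
}

#' Look up a built-in scheme by name
#'
#' @param name `"xylan"` or `"glucan"`, or a `migkin_scheme` (returned
#'   unchanged).
#' @return A `migkin_scheme`.
#' @export
get_scheme <- function(name) {
  if (inherits(name, "migkin_scheme")) return(name)
  switch(as.character(name),
         xylan  = build_xylan_scheme(),
         glucan = build_glucan_scheme(),
         stop("unknown scheme '", name,
              "'; built-in fixtures are: xylan, glucan"))
}

#' Validate the structural invariants of a scheme
#'
#' Checks that species ids are unique, every reaction connects two
#' distinct known species, migrations conserve the acetyl count while
#' hydrolyses reduce it by exactly one, the declared free rate symbols
#' match the symbols used by reactions (no orphans, no duplicates), the
#' reaction graph is weakly connected, and every acetylated species has a
#' directed path to a fully deacetylated species.
#'
#' @param scheme A `migkin_scheme`.
#' @return Character vector of violation messages; empty if the scheme is
#'   valid.  Violations are returned, not raised.
#' @export
validate_scheme <- function(scheme) {
  msgs <- character(0)
  sp <- names(scheme$species)
  if (anyDuplicated(sp)) {
    msgs <- c(msgs, paste0("duplicate species id(s): ",
                           paste(unique(sp[duplicated(sp)]), collapse = ", ")))
  }
  counts <- acetyl_counts(scheme)
  rx <- scheme$reactions
  for (i in seq_len(nrow(rx))) {
    r <- rx[i, ]
    lbl <- sprintf("reaction %d (%s -> %s, %s)", i, r$reactant, r$product,
                   r$rate_symbol)
    if (!r$reactant %in% sp || !r$product %in% sp) {
      msgs <- c(msgs, paste0(lbl, ": unknown species"))
      next
    }
    if (r$reactant == r$product) {
      msgs <- c(msgs, paste0(lbl, ": reactant equals product"))
    }
    if (!r$kind %in% reaction_kinds()) {
      msgs <- c(msgs, paste0(lbl, ": unknown kind '", r$kind, "'"))
      next
    }
    dn <- counts[[r$reactant]] - counts[[r$product]]
    if (grepl("^migration", r$kind) && dn != 0L) {
      msgs <- c(msgs, paste0(lbl, ": migration changes acetyl count by ", -dn))
    }
    if (grepl("^hydrolysis", r$kind) && dn != 1L) {
      msgs <- c(msgs, paste0(lbl, ": hydrolysis must remove exactly 1 acetyl",
                             " (removes ", dn, ")"))
    }
  }
  used <- unique(rx$rate_symbol)
  orphan <- setdiff(scheme$rate_symbols, used)
  if (length(orphan)) {
    msgs <- c(msgs, paste0("rate symbol(s) never used by a reaction: ",
                           paste(orphan, collapse = ", ")))
  }
  undeclared <- setdiff(used, scheme$rate_symbols)
  if (length(undeclared)) {
    msgs <- c(msgs, paste0("rate symbol(s) used but not declared: ",
                           paste(undeclared, collapse = ", ")))
  }
  if (anyDuplicated(scheme$rate_symbols)) {
    msgs <- c(msgs, "rate_symbols contains duplicates")
  }
  ok_edges <- rx$reactant %in% sp & rx$product %in% sp
  if (length(sp) > 1) {
    comp <- .components_undirected(sp, rx[ok_edges, , drop = FALSE])
    if (max(comp) > 1) {
      msgs <- c(msgs, "reaction graph is not weakly connected")
    }
  }
  terminal <- sp[counts == 0L]
  if (!length(terminal)) {
    msgs <- c(msgs, "scheme has no fully deacetylated species")
  } else {
    reach <- .reaches_directed(sp, rx[ok_edges, , drop = FALSE], terminal)
    stranded <- sp[counts > 0L & !reach]
    if (length(stranded)) {
      msgs <- c(msgs, paste0("species without a path to full deacetylation: ",
                             paste(stranded, collapse = ", ")))
    }
  }
  msgs
}

# connected components of the undirected reaction graph
.components_undirected <- function(sp, rx) {
  comp <- setNames(seq_along(sp), sp)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(rx))) {
      a <- rx$reactant[i]; b <- rx$product[i]
      m <- min(comp[[a]], comp[[b]])
      if (comp[[a]] != m || comp[[b]] != m) {
        comp[comp == comp[[a]] | comp == comp[[b]]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, sort(unique(comp)))
}

# which species have a directed path into `targets`
.reaches_directed <- function(sp, rx, targets) {
  reach <- setNames(sp %in% targets, sp)
  repeat {
    new <- reach
    for (i in seq_len(nrow(rx))) {
      if (reach[[rx$product[i]]]) new[[rx$reactant[i]]] <- TRUE
    }
    if (identical(new, reach)) break
    reach <- new
  }
  reach
}

#' Write a scheme to a JSON file
#'
#' The on-disk format has top-level keys `name`, `species` (array of
#' `{id, acetyl_positions}`), `reactions` and `rate_symbols`, and
#' round-trips through [read_scheme()] byte-identically.
#'
#' @param scheme A `migkin_scheme`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  obj <- list(
    name = scheme$name,
    species = lapply(names(scheme$species), function(id) {
      list(id = id, acetyl_positions = I(scheme$species[[id]]))
    }),
    reactions = scheme$reactions,
    rate_symbols = I(scheme$rate_symbols)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a scheme from a JSON file
#'
#' @param path Path to a JSON file written by [write_scheme()] (or in the
#'   same format).
#' @return A `migkin_scheme`.
#' @export
read_scheme <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (key in c("name", "species", "reactions")) {
    if (is.null(obj[[key]])) stop("scheme file missing key '", key, "'")
  }
  species <- list()
  for (s in obj$species) {
    species[[s$id]] <- unlist(s$acetyl_positions) %||% character(0)
  }
  rx <- do.call(rbind, lapply(obj$reactions, function(r) {
    data.frame(reactant = r$reactant, product = r$product,
               rate_symbol = r$rate_symbol, kind = r$kind,
               ph_sensitive = r$ph_sensitive %||% TRUE,
               stringsAsFactors = FALSE)
  }))
  new_scheme(obj$name, species, rx,
             rate_symbols = unlist(obj$rate_symbols))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
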