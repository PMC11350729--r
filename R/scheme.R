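#' Build a mass-action kinetic scheme
#'
#' A kinetic scheme is a set of species connected by reversible mass-action
#' reactions, together with the conserved moieties (E, S, I, A) each species
#' carries. Four built-in schemes cover the binding models used throughout the
#' package:
#'
#' * `"ONE_STEP"` — two-state binding `E + S <-> ES` governed by `k1`/`km1`.
#' * `"INDUCED_FIT"` — binding followed by a conformational (loop-closing)
#'   step: `E + S <-> ES <-> ES_c`, with the isomerisation governed by
#'   `kconf`/`kmconf`.
#' * `"CONF_SELECTION"` — the conformational step precedes binding:
#'   `E <-> E_c`, `E_c + S <-> ES_c`.
#' * `"TERNARY"` — independent binding of two products I (ImGP-like, `k2`/`km2`)
#'   and A (AICAR-like, `k3`/`km3`) to the free enzyme and to the opposite
#'   binary complex, followed by a conformational step that stabilises the
#'   ternary complex (`k4`/`km4`). By default the association/dissociation
#'   constants for a ligand are shared between the apo enzyme and the binary
#'   complex (the simplest binding model); `tie_binding = FALSE` unties them,
#'   introducing `k2b`/`km2b` and `k3b`/`km3b`.
#'
#' Custom schemes are built from a species table and a reaction table and are
#' validated for moiety balance.
#'
#' Rate-constant names use `m` for the reverse direction (`km1` is the
#' dissociation constant paired with `k1`). Bimolecular constants are in
#' 1/(uM s), unimolecular in 1/s.
#'
#' @param builtin_id One of `"ONE_STEP"`, `"INDUCED_FIT"`, `"CONF_SELECTION"`,
#'   `"TERNARY"`, or `NULL` to build a custom scheme.
#' @param species For custom schemes, a data frame with columns `name`, `role`
#'   (one of `"enzyme-state"`, `"ligand"`, `"complex"`) and one integer column
#'   per conserved moiety (e.g. `E`, `S`).
#' @param reactions For custom schemes, a data frame with list-columns
#'   `reactants` and `products` (1-2 species names each) and character columns
#'   `kf_name`, `kr_name`. A reverse name of `NA` or `""` marks an
#'   irreversible reaction.
#' @param tie_binding For `"TERNARY"`: share each ligand's binding constants
#'   between apo enzyme and binary complex (default `TRUE`).
#'
#' @return An object of class `kinetic_scheme`: a list with `builtin_id`,
#'   a `species` tibble, a moiety count matrix (`moieties`, species x moiety;
#'   its columns are the conservation vectors), a `reactions` tibble and the
#'   vector of rate-constant names (`rate_names`).
#' @examples
#' sc <- build_scheme("ONE_STEP")
#' sc$reactions
#' @export
build_scheme <- function(builtin_id = NULL, species = NULL, reactions = NULL,
                         tie_binding = TRUE) {
  if (!is.null(builtin_id)) {
    builtin_id <- match.arg(toupper(builtin_id),
                            c("ONE_STEP", "INDUCED_FIT", "CONF_SELECTION", "TERNARY"))
    def <- builtin_scheme_def(builtin_id, tie_binding)
    species <- def$species
    reactions <- def$reactions
  } else {
    if (is.null(species) || is.null(reactions)) {
      stop("either `builtin_id` or both `species` and `reactions` must be given",
           call. = FALSE)
    }
    builtin_id <- "CUSTOM"
  }
  new_kinetic_scheme(builtin_id, species, reactions)
}

builtin_scheme_def <- function(id, tie_binding = TRUE) {
  sp <- function(name, role, ...) {
    m <- c(...)
    tibble::tibble(name = name, role = role, !!!as.list(m))
  }
  rx <- function(reactants, products, kf, kr) {
    tibble::tibble(reactants = list(reactants), products = list(products),
                   kf_name = kf, kr_name = kr)
  }
  switch(id,
    ONE_STEP = list(
      species = dplyr::bind_rows(
        sp("E", "enzyme-state", E = 1L, S = 0L),
        sp("S", "ligand", E = 0L, S = 1L),
        sp("ES", "complex", E = 1L, S = 1L)),
      reactions = dplyr::bind_rows(
        rx(c("E", "S"), "ES", "k1", "km1"))),
    INDUCED_FIT = list(
      species = dplyr::bind_rows(
        sp("E", "enzyme-state", E = 1L, S = 0L),
        sp("S", "ligand", E = 0L, S = 1L),
        sp("ES", "complex", E = 1L, S = 1L),
        sp("ES_c", "complex", E = 1L, S = 1L)),
      reactions = dplyr::bind_rows(
        rx(c("E", "S"), "ES", "k1", "km1"),
        rx("ES", "ES_c", "kconf", "kmconf"))),
    CONF_SELECTION = list(
      species = dplyr::bind_rows(
        sp("E", "enzyme-state", E = 1L, S = 0L),
        sp("E_c", "enzyme-state", E = 1L, S = 0L),
        sp("S", "ligand", E = 0L, S = 1L),
        sp("ES_c", "complex", E = 1L, S = 1L)),
      reactions = dplyr::bind_rows(
        rx("E", "E_c", "kconf", "kmconf"),
        rx(c("E_c", "S"), "ES_c", "k1", "km1"))),
    TERNARY = {
      k2b <- if (tie_binding) c("k2", "km2") else c("k2b", "km2b")
      k3b <- if (tie_binding) c("k3", "km3") else c("k3b", "km3b")
      list(
        species = dplyr::bind_rows(
          sp("E", "enzyme-state", E = 1L, I = 0L, A = 0L),
          sp("I", "ligand", E = 0L, I = 1L, A = 0L),
          sp("A", "ligand", E = 0L, I = 0L, A = 1L),
          sp("EI", "complex", E = 1L, I = 1L, A = 0L),
          sp("EA", "complex", E = 1L, I = 0L, A = 1L),
          sp("EIA", "complex", E = 1L, I = 1L, A = 1L),
          sp("EIA_c", "complex", E = 1L, I = 1L, A = 1L)),
        reactions = dplyr::bind_rows(
          rx(c("E", "I"), "EI", "k2", "km2"),
          rx(c("E", "A"), "EA", "k3", "km3"),
          rx(c("EA", "I"), "EIA", k2b[1], k2b[2]),
          rx(c("EI", "A"), "EIA", k3b[1], k3b[2]),
          rx("EIA", "EIA_c", "k4", "km4")))
    })
}

new_kinetic_scheme <- function(builtin_id, species, reactions) {
  species <- tibble::as_tibble(species)
  reactions <- tibble::as_tibble(reactions)
  if (anyDuplicated(species$name)) {
    stop("duplicate species name: ",
         paste(unique(species$name[duplicated(species$name)]), collapse = ", "),
         call. = FALSE)
  }
  moiety_cols <- setdiff(names(species), c("name", "role"))
  if (length(moiety_cols) == 0L) stop("species table has no moiety columns", call. = FALSE)
  M <- as.matrix(species[moiety_cols])
  storage.mode(M) <- "double"
  rownames(M) <- species$name
  if (any(M < 0)) stop("moiety counts must be >= 0", call. = FALSE)
  bad_complex <- species$role == "complex" & rowSums(M) < 2
  if (any(bad_complex)) {
    stop("complex species must carry >= 2 moieties: ",
         paste(species$name[bad_complex], collapse = ", "), call. = FALSE)
  }
  if (!all(c("reactants", "products", "kf_name", "kr_name") %in% names(reactions))) {
    stop("reactions need columns reactants, products, kf_name, kr_name", call. = FALSE)
  }
  if (!is.list(reactions$reactants)) reactions$reactants <- as.list(reactions$reactants)
  if (!is.list(reactions$products)) reactions$products <- as.list(reactions$products)
  for (j in seq_len(nrow(reactions))) {
    r <- reactions$reactants[[j]]; p <- reactions$products[[j]]
    if (length(r) < 1 || length(r) > 2 || length(p) < 1 || length(p) > 2) {
      stop("reaction ", j, ": 1-2 reactants and 1-2 products required", call. = FALSE)
    }
    unknown <- setdiff(c(r, p), species$name)
    if (length(unknown)) {
      stop("reaction ", j, " references unknown species: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    bal <- colSums(M[r, , drop = FALSE]) - colSums(M[p, , drop = FALSE])
    if (any(abs(bal) > 0)) {
      stop("reaction ", j, " (", paste(r, collapse = " + "), " <-> ",
           paste(p, collapse = " + "), ") is not moiety-balanced", call. = FALSE)
    }
  }
  reactions$kr_name[is.na(reactions$kr_name)] <- ""
  rate_names <- unique(c(reactions$kf_name, reactions$kr_name))
  rate_names <- rate_names[nzchar(rate_names)]
  structure(
    list(builtin_id = builtin_id, species = species, moieties = M,
         reactions = reactions, rate_names = rate_names),
    class = "kinetic_scheme")
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("<kinetic_scheme> ", x$builtin_id, ": ", nrow(x$species), " species, ",
      nrow(x$reactions), " reactions\n", sep = "")
  for (j in seq_len(nrow(x$reactions))) {
    kr <- x$reactions$kr_name[j]
    arrow <- if (nzchar(kr)) " <-> " else " --> "
    cat("  ", paste(x$reactions$reactants[[j]], collapse = " + "), arrow,
        paste(x$reactions$products[[j]], collapse = " + "),
        "  [", x$reactions$kf_name[j],
        if (nzchar(kr)) paste0("/", kr), "]\n", sep = "")
  }
  invisible(x)
}

#' Named rate-constant sets and derived equilibrium constants
#'
#' `rate_params()` assembles a named vector of rate constants (values in uM
#' and s units: bimolecular constants in 1/(uM s), unimolecular in 1/s), with
#' optional standard errors attached as an attribute. `derived_constants()`
#' recomputes the derived equilibrium quantities from a rate set — they are
#' never stored independently: `KD1 = km1/k1` (uM), and for the ternary
#' scheme `KD2 = km2/k2`, `KD3 = km3/k3` (uM) and the dimensionless
#' loop-closing constant `K4 = k4/km4`.
#'
#' @param ... Named rate constants, e.g. `k1 = 0.1, km1 = 1`.
#' @param se Optional named vector of standard errors.
#' @return `rate_params()`: a named numeric vector of class `sf_rates`;
#'   `derived_constants()`: a tibble with columns `name`, `value`, `unit`.
#' @examples
#' p <- rate_params(k1 = 0.1, km1 = 1)
#' derived_constants(p)
#' @export
rate_params <- function(..., se = NULL) {
  v <- c(...)
  if (is.null(names(v)) || any(!nzchar(names(v)))) {
    stop("all rate constants must be named", call. = FALSE)
  }
  if (any(v < 0)) stop("rate constants must be >= 0", call. = FALSE)
  if (!is.null(se)) {
    stopifnot(all(names(se) %in% names(v)))
    attr(v, "se") <- se
  }
  class(v) <- "sf_rates"
  v
}

#' @rdname rate_params
#' @param params A named numeric vector of rate constants.
#' @export
derived_constants <- function(params) {
  out <- list()
  has <- function(nm) all(nm %in% names(params)) && all(params[nm] > 0 | params[nm] >= 0)
  if (all(c("k1", "km1") %in% names(params)) && params[["k1"]] > 0) {
    out$KD1 <- c(params[["km1"]] / params[["k1"]], "uM")
  }
  if (all(c("k2", "km2") %in% names(params)) && params[["k2"]] > 0) {
    out$KD2 <- c(params[["km2"]] / params[["k2"]], "uM")
  }
  if (all(c("k3", "km3") %in% names(params)) && params[["k3"]] > 0) {
    out$KD3 <- c(params[["km3"]] / params[["k3"]], "uM")
  }
  if (all(c("k4", "km4") %in% names(params)) && params[["km4"]] > 0) {
    out$K4 <- c(params[["k4"]] / params[["km4"]], "")
  }
  if (all(c("kconf", "kmconf") %in% names(params)) && params[["kmconf"]] > 0) {
    out$Kconf <- c(params[["kconf"]] / params[["kmconf"]], "")
  }
  tibble::tibble(
    name = names(out),
    value = unname(vapply(out, function(x) as.numeric(x[1]), numeric(1))),
    unit = unname(vapply(out, function(x) x[2], character(1))))
}

# Resolve scheme rate names against a params vector; error on missing.
scheme_rate_values <- function(scheme, params) {
  missing <- setdiff(scheme$rate_names, names(params))
  if (length(missing)) {
    stop("missing rate constants: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  kf <- unname(params[scheme$reactions$kf_name])
  kr <- ifelse(nzchar(scheme$reactions$kr_name),
               unname(params[replace(scheme$reactions$kr_name,
                                     !nzchar(scheme$reactions$kr_name), NA)]),
               0)
  kr[is.na(kr)] <- 0
  list(kf = as.numeric(kf), kr = as.numeric(kr))
}

# Stoichiometry matrix (species x reactions) and index lists, precomputed once
# per integration.
scheme_topology <- function(scheme) {
  spn <- scheme$species$name
  nr <- nrow(scheme$reactions)
  N <- matrix(0, length(spn), nr, dimnames = list(spn, NULL))
  ridx <- vector("list", nr); pidx <- vector("list", nr)
  for (j in seq_len(nr)) {
    r <- match(scheme$reactions$reactants[[j]], spn)
    p <- match(scheme$reactions$products[[j]], spn)
    for (i in r) N[i, j] <- N[i, j] - 1
    for (i in p) N[i, j] <- N[i, j] + 1
    ridx[[j]] <- r; pidx[[j]] <- p
  }
  list(N = N, ridx = ridx, pidx = pidx)
}
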