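#' Construct a constraint-based metabolic model
#'
#' A metabolic model is the raw material of flux balance analysis: a
#' stoichiometric matrix `S` (m metabolites by n reactions), flux bounds
#' `lb`/`ub`, an objective coefficient vector `obj` (typically the biomass
#' reaction indicator), and a right-hand side `b` for the mass-balance
#' constraints `S v = b` (all zeros at steady state).
#'
#' Inequality (coupling) constraints that some model files carry in addition
#' to mass balance are stored separately in `aux`, a list with a coefficient
#' matrix `C`, a sense vector (`"L"` for <=, `"G"` for >=) and a right-hand
#' side, so that such files remain loadable without forcing them into `S`.
#'
#' @param S stoichiometric matrix, m x n (dense or `Matrix` sparse).
#' @param lb,ub numeric lower/upper flux bounds, length n. `-Inf`/`Inf`
#'   allowed.
#' @param obj numeric objective coefficients, length n.
#' @param b right-hand side of the balance constraints, length m; defaults
#'   to zeros (steady state).
#' @param reaction_ids,metabolite_ids character identifiers; generated as
#'   `R1..Rn` / `M1..Mm` when omitted. Must be unique, non-empty and free of
#'   whitespace (MPS round-trip safety).
#' @param objective_sense `"maximize"` (default) or `"minimize"`.
#' @param aux optional auxiliary inequality constraints: a list with
#'   elements `C` (k x n matrix), `sense` (character, `"L"`/`"G"`), `rhs`
#'   (length k) and optionally `ids`.
#' @return An object of class `metabolic_model`.
#' @seealso [validate_model()], [read_mps()], [as_metabolic_model()],
#'   [toy_model()]
#' @examples
#' m <- metabolic_model(S = matrix(c(1, -1, -1), 1, 3),
#'                      lb = c(0, 0, 0), ub = c(10, 10, 5),
#'                      obj = c(0, 1, 0))
#' m
#' @export
metabolic_model <- function(S, lb, ub, obj,
                            b = NULL,
                            reaction_ids = NULL,
                            metabolite_ids = NULL,
                            objective_sense = c("maximize", "minimize"),
                            aux = NULL) {
  # general CSC storage: unit-diagonal and symmetric specializations of
  # Matrix() would break the triplet round-trips used by the writers
  S <- methods::as(methods::as(methods::as(Matrix::Matrix(S, sparse = TRUE),
                                           "dMatrix"),
                               "generalMatrix"), "CsparseMatrix")
  m <- nrow(S)
  n <- ncol(S)
  if (is.null(b)) b <- numeric(m)
  if (is.null(reaction_ids)) reaction_ids <- paste0("R", seq_len(n))
  if (is.null(metabolite_ids)) metabolite_ids <- paste0("M", seq_len(m))
  objective_sense <- match.arg(objective_sense)
  if (!is.null(aux)) {
    aux$C <- as.matrix(aux$C)
    if (is.null(aux$ids)) aux$ids <- paste0("AUX", seq_len(nrow(aux$C)))
    aux$rhs <- as.numeric(aux$rhs)
  }
  model <- structure(
    list(S = S,
         lb = as.numeric(lb), ub = as.numeric(ub),
         obj = as.numeric(obj), b = as.numeric(b),
         reaction_ids = as.character(reaction_ids),
         metabolite_ids = as.character(metabolite_ids),
         objective_sense = objective_sense,
         aux = aux),
    class = "metabolic_model")
  validate_model(model)
  model
}

#' Validate a metabolic model
#'
#' Checks the structural invariants: matching dimensions between `S`, the
#' bound vectors, the objective and the identifier lists; `lb <= ub`
#' elementwise; unique, non-empty, whitespace-free identifiers; and
#' consistent auxiliary constraints. Throws an informative error on the
#' first violation.
#'
#' @param model a `metabolic_model`.
#' @return The model, invisibly, when valid.
#' @export
validate_model <- function(model) {
  rep <- model_validation_report(model)
  if (!rep$valid) stop("invalid metabolic model: ", rep$errors[[1L]], call. = FALSE)
  invisible(model)
}

#' Produce a validation report for a model
#'
#' Like [validate_model()] but never throws: returns a list with `valid`
#' (logical) and `errors` (character vector), suitable for serialization as
#' JSON.
#'
#' @inheritParams validate_model
#' @return list with elements `valid`, `errors`, `n_reactions`,
#'   `n_metabolites`.
#' @export
model_validation_report <- function(model) {
  errs <- character(0)
  note <- function(msg) errs[[length(errs) + 1L]] <<- msg
  if (!inherits(model, "metabolic_model")) note("not a metabolic_model object")
  m <- nrow(model$S); n <- ncol(model$S)
  if (length(model$lb) != n) note(sprintf("lb has length %d, expected n=%d", length(model$lb), n))
  if (length(model$ub) != n) note(sprintf("ub has length %d, expected n=%d", length(model$ub), n))
  if (length(model$obj) != n) note(sprintf("objective has length %d, expected n=%d", length(model$obj), n))
  if (length(model$b) != m) note(sprintf("b has length %d, expected m=%d", length(model$b), m))
  if (length(model$reaction_ids) != n) note("reaction_ids length differs from ncol(S)")
  if (length(model$metabolite_ids) != m) note("metabolite_ids length differs from nrow(S)")
  if (length(errs) == 0L) {
    bad <- which(model$lb > model$ub)
    if (length(bad))
      note(sprintf("lb > ub for reaction '%s' (%g > %g)",
                   model$reaction_ids[bad[1L]], model$lb[bad[1L]], model$ub[bad[1L]]))
    for (ids in list(model$reaction_ids, model$metabolite_ids)) {
      if (anyDuplicated(ids)) note(sprintf("duplicated identifier '%s'", ids[duplicated(ids)][1L]))
      if (any(!nzchar(ids))) note("empty identifier")
      if (any(grepl("[[:space:]]", ids))) note("identifier contains whitespace")
    }
    if (any(!is.finite(model$obj))) note("non-finite objective coefficient")
    if (!is.null(model$aux)) {
      if (ncol(model$aux$C) != n) note("auxiliary constraint matrix has wrong column count")
      if (length(model$aux$rhs) != nrow(model$aux$C)) note("auxiliary rhs length mismatch")
      if (!all(model$aux$sense %in% c("L", "G"))) note("auxiliary senses must be 'L' or 'G'")
    }
  }
  list(valid = length(errs) == 0L, errors = errs,
       n_reactions = n, n_metabolites = m)
}

#' Convert a structured (COBRA-style) container to a metabolic model
#'
#' Accepts a plain list using the COBRA field convention: `S`, `lb`, `ub`,
#' `c` (objective), and optionally `b`, `rxns`, `mets`, `osense`. `S` may be
#' a dense matrix, a `Matrix` sparse matrix, or a triplet list with fields
#' `i`, `j`, `x` and `dims`. Absent `b` defaults to zeros; absent
#' identifiers are generated; an absent objective becomes the zero vector
#' with a warning (no objective defined).
#'
#' @param x a list with COBRA-named fields.
#' @return A validated `metabolic_model`.
#' @export
as_metabolic_model <- function(x) {
  if (inherits(x, "metabolic_model")) return(validate_model(x))
  if (!is.list(x)) stop("expected a list with COBRA-style fields", call. = FALSE)
  for (f in c("S", "lb", "ub")) {
    if (is.null(x[[f]])) stop(sprintf("structured container is missing field '%s'", f), call. = FALSE)
  }
  S <- x$S
  if (is.list(S) && !is.null(S$i)) {
    S <- Matrix::sparseMatrix(i = as.integer(S$i), j = as.integer(S$j),
                              x = as.numeric(S$x), dims = as.integer(S$dims))
  } else {
    S <- Matrix::Matrix(as.matrix(S), sparse = TRUE)
  }
  n <- ncol(S)
  obj <- x$c
  if (is.null(obj)) {
    warning("container has no objective vector 'c'; using zeros (no objective)",
            call. = FALSE)
    obj <- numeric(n)
  }
  if (length(x$lb) != n || length(x$ub) != n || length(obj) != n)
    stop(sprintf("dimension mismatch: S is %dx%d but lb/ub/c have lengths %d/%d/%d",
                 nrow(S), n, length(x$lb), length(x$ub), length(obj)), call. = FALSE)
  sense <- x$osense
  sense <- if (is.null(sense)) "maximize"
           else if (identical(sense, -1) || identical(sense, "max") || identical(sense, "maximize")) "maximize"
           else "minimize"
  metabolic_model(S = S, lb = x$lb, ub = x$ub, obj = obj, b = x$b,
                  reaction_ids = x$rxns, metabolite_ids = x$mets,
                  objective_sense = sense)
}

#' Read / write a structured model container (JSON archive)
#'
#' The container is a key/value archive using COBRA field names (`S` as a
#' triplet list, `lb`, `ub`, `c`, `b`, `rxns`, `mets`, `osense`), stored as
#' JSON. It is the text-format sibling of the `.mat` exports used by COBRA
#' toolboxes and is what [fluxvar_cli()]'s `convert` subcommand consumes.
#'
#' @param path file path of the JSON container.
#' @return `read_model_container()` returns a validated `metabolic_model`.
#' @export
read_model_container <- function(path) {
  if (!file.exists(path)) stop("container file not found: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_metabolic_model(x)
}

#' @rdname read_model_container
#' @param model a `metabolic_model` to serialize.
#' @export
write_model_container <- function(model, path) {
  validate_model(model)
  trip <- Matrix::mat2triplet(model$S)
  x <- list(S = list(i = trip$i, j = trip$j, x = trip$x, dims = dim(model$S)),
            lb = model$lb, ub = model$ub, c = model$obj, b = model$b,
            rxns = model$reaction_ids, mets = model$metabolite_ids,
            osense = model$objective_sense)
  jsonlite::write_json(x, path, auto_unbox = FALSE, digits = NA, null = "null")
  invisible(path)
}

#' @export
print.metabolic_model <- function(x, ...) {
  m <- nrow(x$S); n <- ncol(x$S)
  cat(sprintf("Metabolic model: %d metabolites x %d reactions (%s)\n",
              m, n, x$objective_sense))
  nobj <- sum(x$obj != 0)
  if (nobj == 1L) {
    cat(sprintf("  objective: %s\n", x$reaction_ids[which(x$obj != 0)]))
  } else {
    cat(sprintf("  objective: %d nonzero coefficients\n", nobj))
  }
  nrev <- sum(x$lb < 0)
  cat(sprintf("  reversible reactions (lb < 0): %d\n", nrev))
  if (!is.null(x$aux))
    cat(sprintf("  auxiliary inequality constraints: %d\n", nrow(x$aux$C)))
  invisible(x)
}

#' @export
dim.metabolic_model <- function(x) dim(x$S)
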