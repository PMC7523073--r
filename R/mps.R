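# MPS reading and writing. Free-format is primary (genome-scale reaction
# identifiers exceed the 8-character fields of the fixed layout); the
# fixed dialect is read through the same whitespace tokenizer (best effort)
# and enforced only on write. Bounds with magnitude >= 1e30 are infinite.

.mps_inf <- 1e30

#' Read a metabolic model from an MPS file
#'
#' Parses the standard LP sections (`ROWS`, `COLUMNS`, `RHS`, `BOUNDS`,
#' with optional `NAME`/`OBJSENSE`/`ENDATA`). The single `N` row becomes
#' the objective; `E` rows become mass-balance rows of `S` with
#' right-hand side `b`; `L`/`G` rows are kept as auxiliary inequality
#' constraints so coupled-model files remain loadable. Missing `BOUNDS`
#' entries default to `[0, +Inf)` per MPS convention; values of magnitude
#' `>= 1e30` are treated as infinite. `RANGES` sections and integer
#' markers are unsupported and raise an error naming the offending line.
#'
#' @param path MPS file path.
#' @param dialect `"free"` (default) or `"fixed"`; both are read through
#'   the same whitespace tokenizer.
#' @return A validated `metabolic_model`. When the file carries no
#'   `OBJSENSE`, the sense defaults to maximization, the usual convention
#'   for biomass objectives in this setting.
#' @seealso [write_mps()]
#' @export
read_mps <- function(path, dialect = c("free", "fixed")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("MPS file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  perr <- function(ln, msg)
    stop(sprintf("MPS parse error at line %d: %s", ln, msg), call. = FALSE)

  section <- NA_character_
  seen <- character(0)
  obj_row <- NA_character_
  obj_sense <- NULL
  row_type <- new.env(parent = emptyenv())   # row name -> E/L/G
  row_order <- character(0)
  col_order <- character(0)
  col_idx <- new.env(parent = emptyenv())
  entries_i <- character(0); entries_j <- character(0); entries_x <- numeric(0)
  obj_coef <- new.env(parent = emptyenv())
  rhs_val <- new.env(parent = emptyenv())
  bnd <- new.env(parent = emptyenv())   # per column: c(lb, ub) with NA = default
  expect_objsense_value <- FALSE

  num <- function(tok, ln) {
    x <- suppressWarnings(as.numeric(tok))
    if (is.na(x)) perr(ln, sprintf("expected a number, got '%s'", tok))
    x
  }

  for (ln in seq_along(lines)) {
    raw <- lines[[ln]]
    if (!nzchar(raw) || startsWith(raw, "*")) next
    indented <- grepl("^[ \t]", raw)
    toks <- strsplit(trimws(raw), "[ \t]+")[[1]]
    if (!length(toks)) next
    if (!indented) {
      head <- toupper(toks[[1]])
      if (head %in% c("NAME", "ROWS", "COLUMNS", "RHS", "RANGES", "BOUNDS",
                      "OBJSENSE", "ENDATA")) {
        section <- head
        seen <- c(seen, head)
        if (head == "RANGES" && length(toks) > 1) {}
        if (head == "OBJSENSE" && length(toks) > 1) {
          obj_sense <- toupper(toks[[2]])
        } else if (head == "OBJSENSE") {
          expect_objsense_value <- TRUE
        }
        if (head == "ENDATA") break
        next
      }
      # data line without indentation (free MPS allows it)
    }
    if (isTRUE(expect_objsense_value)) {
      obj_sense <- toupper(toks[[1]])
      expect_objsense_value <- FALSE
      next
    }
    if (is.na(section)) perr(ln, "data before any section header")
    switch(section,
      NAME = NULL,
      ROWS = {
        if (length(toks) < 2) perr(ln, "ROWS entry needs a type and a name")
        ty <- toupper(toks[[1]]); nm <- toks[[2]]
        if (ty == "N") {
          if (!is.na(obj_row)) perr(ln, "more than one objective (N) row")
          obj_row <- nm
        } else if (ty %in% c("E", "L", "G")) {
          row_type[[nm]] <- ty
          row_order <- c(row_order, nm)
        } else perr(ln, sprintf("unknown row type '%s'", ty))
      },
      COLUMNS = {
        if (length(toks) >= 3 && toupper(toks[[3]]) == "'MARKER'" ||
            any(toupper(toks) == "'MARKER'"))
          perr(ln, "integer markers are not supported")
        if (length(toks) < 3 || length(toks) %% 2 == 0)
          perr(ln, "COLUMNS entry needs a column name and row/value pairs")
        colnm <- toks[[1]]
        if (is.null(col_idx[[colnm]])) {
          col_idx[[colnm]] <- TRUE
          col_order <- c(col_order, colnm)
        }
        for (k in seq(2, length(toks), by = 2)) {
          rw <- toks[[k]]; val <- num(toks[[k + 1]], ln)
          if (identical(rw, obj_row)) {
            obj_coef[[colnm]] <- val
          } else if (!is.null(row_type[[rw]])) {
            entries_i <- c(entries_i, rw)
            entries_j <- c(entries_j, colnm)
            entries_x <- c(entries_x, val)
          } else perr(ln, sprintf("unknown row '%s'", rw))
        }
      },
      RHS = {
        if (length(toks) < 3 || length(toks) %% 2 == 0)
          perr(ln, "RHS entry needs a set name and row/value pairs")
        for (k in seq(2, length(toks), by = 2)) {
          rw <- toks[[k]]; val <- num(toks[[k + 1]], ln)
          if (identical(rw, obj_row)) next   # objective constant, ignored
          if (is.null(row_type[[rw]])) perr(ln, sprintf("unknown row '%s'", rw))
          rhs_val[[rw]] <- val
        }
      },
      RANGES = perr(ln, "ranged rows (RANGES section) are not supported"),
      BOUNDS = {
        if (length(toks) < 3) perr(ln, "BOUNDS entry needs a type, set and column")
        ty <- toupper(toks[[1]]); colnm <- toks[[3]]
        if (is.null(col_idx[[colnm]]))
          perr(ln, sprintf("bound for unknown column '%s'", colnm))
        cur <- bnd[[colnm]]
        if (is.null(cur)) cur <- c(NA_real_, NA_real_)
        needs_val <- ty %in% c("UP", "LO", "FX")
        if (needs_val && length(toks) < 4) perr(ln, "bound type needs a value")
        val <- if (needs_val) num(toks[[4]], ln) else NA_real_
        if (needs_val && abs(val) >= .mps_inf) val <- sign(val) * Inf
        if (ty == "UP") {
          cur[2] <- val
          if (val < 0 && is.na(cur[1])) cur[1] <- -Inf   # classic MPS quirk
        } else if (ty == "LO") cur[1] <- val
        else if (ty == "FX") cur[1] <- cur[2] <- val
        else if (ty == "FR") { cur[1] <- -Inf; cur[2] <- Inf }
        else if (ty == "MI") cur[1] <- -Inf
        else if (ty == "PL") cur[2] <- Inf
        else perr(ln, sprintf("unsupported bound type '%s'", ty))
        bnd[[colnm]] <- cur
      },
      perr(ln, sprintf("unexpected data in section %s", section)))
  }

  for (req in c("ROWS", "COLUMNS")) {
    if (!req %in% seen)
      stop(sprintf("MPS parse error: missing required section %s", req), call. = FALSE)
  }
  if (is.na(obj_row))
    stop("MPS parse error: no objective (N) row", call. = FALSE)
  n <- length(col_order)
  if (n == 0L) stop("MPS parse error: no columns", call. = FALSE)

  eq_rows <- row_order[vapply(row_order, function(r) row_type[[r]] == "E", TRUE)]
  ineq_rows <- setdiff(row_order, eq_rows)
  ri <- match(entries_i, eq_rows)
  ci <- match(entries_j, col_order)
  in_eq <- !is.na(ri)
  S <- Matrix::sparseMatrix(i = ri[in_eq], j = ci[in_eq], x = entries_x[in_eq],
                            dims = c(length(eq_rows), n))
  b <- vapply(eq_rows, function(r) {
    v <- rhs_val[[r]]; if (is.null(v)) 0 else v
  }, 0)

  aux <- NULL
  if (length(ineq_rows)) {
    ai <- match(entries_i, ineq_rows)
    in_aux <- !is.na(ai)
    C <- matrix(0, length(ineq_rows), n)
    C[cbind(ai[in_aux], ci[in_aux])] <- entries_x[in_aux]
    aux <- list(C = C,
                sense = vapply(ineq_rows, function(r) row_type[[r]], ""),
                rhs = vapply(ineq_rows, function(r) {
                  v <- rhs_val[[r]]; if (is.null(v)) 0 else v
                }, 0),
                ids = ineq_rows)
  }

  lb <- numeric(n); ub <- rep(Inf, n)
  for (j in seq_len(n)) {
    cur <- bnd[[col_order[j]]]
    if (!is.null(cur)) {
      if (!is.na(cur[1])) lb[j] <- cur[1]
      if (!is.na(cur[2])) ub[j] <- cur[2]
    }
  }
  obj <- vapply(col_order, function(cn) {
    v <- obj_coef[[cn]]; if (is.null(v)) 0 else v
  }, 0)

  sense <- if (is.null(obj_sense)) "maximize"
           else if (obj_sense %in% c("MAX", "MAXIMIZE")) "maximize" else "minimize"
  metabolic_model(S = S, lb = lb, ub = ub, obj = obj, b = b,
                  reaction_ids = col_order,
                  metabolite_ids = if (length(eq_rows)) eq_rows else character(0),
                  objective_sense = sense, aux = aux)
}

fmt_num <- function(x) {
  ifelse(is.infinite(x), sprintf("%.17g", sign(x) * .mps_inf), sprintf("%.17g", x))
}

#' Write a metabolic model to an MPS file
#'
#' Inverse of [read_mps()]: re-reading the written file reproduces `S`,
#' `lb`, `ub`, `obj` and `b` to full double precision (`%.17g`
#' formatting). Negative lower bounds are written as explicit `LO`
#' entries; infinite bounds are encoded as `1e30` / `MI` / `FR`; the
#' objective sense is recorded in an `OBJSENSE` section.
#'
#' @param model a validated, non-empty `metabolic_model`.
#' @param path output file path.
#' @param dialect `"free"` (default) or `"fixed"`. The fixed dialect
#'   errors when an identifier exceeds its 8-character field, suggesting
#'   the free dialect.
#' @return `path`, invisibly.
#' @export
write_mps <- function(model, path, dialect = c("free", "fixed")) {
  dialect <- match.arg(dialect)
  validate_model(model)
  m <- nrow(model$S); n <- ncol(model$S)
  if (m == 0L || n == 0L)
    stop("refusing to write an empty model (m=0 or n=0)", call. = FALSE)
  ids <- c(model$reaction_ids, model$metabolite_ids,
           if (!is.null(model$aux)) model$aux$ids)
  if (dialect == "fixed" && any(nchar(ids) > 8L))
    stop(sprintf("identifier '%s' exceeds the 8-character fixed-format field; use dialect='free'",
                 ids[nchar(ids) > 8L][1L]), call. = FALSE)

  out <- c(sprintf("NAME          %s", "FLUXVAR_MODEL"),
           "OBJSENSE",
           sprintf("    %s", if (model$objective_sense == "maximize") "MAX" else "MIN"),
           "ROWS",
           " N  OBJ",
           sprintf(" E  %s", model$metabolite_ids))
  if (!is.null(model$aux))
    out <- c(out, sprintf(" %s  %s", model$aux$sense, model$aux$ids))

  out <- c(out, "COLUMNS")
  Sp <- Matrix::mat2triplet(model$S)
  by_col <- split(seq_along(Sp$x), Sp$j)
  for (j in seq_len(n)) {
    rid <- model$reaction_ids[j]
    if (model$obj[j] != 0)
      out <- c(out, sprintf("    %s  OBJ  %s", rid, fmt_num(model$obj[j])))
    ks <- by_col[[as.character(j)]]
    if (!is.null(ks)) {
      out <- c(out, sprintf("    %s  %s  %s", rid,
                            model$metabolite_ids[Sp$i[ks]], fmt_num(Sp$x[ks])))
    }
    if (!is.null(model$aux)) {
      nz <- which(model$aux$C[, j] != 0)
      if (length(nz))
        out <- c(out, sprintf("    %s  %s  %s", rid, model$aux$ids[nz],
                              fmt_num(model$aux$C[nz, j])))
    }
  }

  out <- c(out, "RHS")
  nzb <- which(model$b != 0)
  if (length(nzb))
    out <- c(out, sprintf("    RHS  %s  %s", model$metabolite_ids[nzb],
                          fmt_num(model$b[nzb])))
  if (!is.null(model$aux)) {
    nza <- which(model$aux$rhs != 0)
    if (length(nza))
      out <- c(out, sprintf("    RHS  %s  %s", model$aux$ids[nza],
                            fmt_num(model$aux$rhs[nza])))
  }

  out <- c(out, "BOUNDS")
  for (j in seq_len(n)) {
    lo <- model$lb[j]; up <- model$ub[j]; rid <- model$reaction_ids[j]
    if (lo == 0 && is.infinite(up)) next          # MPS default
    if (lo == up) {
      out <- c(out, sprintf(" FX  BND  %s  %s", rid, fmt_num(lo)))
    } else if (is.infinite(lo) && is.infinite(up)) {
      out <- c(out, sprintf(" FR  BND  %s", rid))
    } else {
      if (is.infinite(lo)) out <- c(out, sprintf(" MI  BND  %s", rid))
      else if (lo != 0) out <- c(out, sprintf(" LO  BND  %s  %s", rid, fmt_num(lo)))
      if (is.finite(up)) out <- c(out, sprintf(" UP  BND  %s  %s", rid, fmt_num(up)))
    }
  }
  out <- c(out, "ENDATA")
  writeLines(out, path)
  invisible(path)
}
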