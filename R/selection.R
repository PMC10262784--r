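#' Resolve an atom selection expression
#'
#' The selection mini-language combines clauses with `and` / `or`
#' (`and` binds tighter) and parentheses:
#' \describe{
#'   \item{`chain <id>`}{atoms of one chain, e.g. `chain U`}
#'   \item{`resid <a>[-<b>] ...`}{author residue numbers; single values and
#'     inclusive ranges may be mixed, e.g. `resid 46-76` or `resid 5 8 10-12`}
#'   \item{`name <n1> [n2 ...]`}{atom names, e.g. `name CA` or `name N CA C O`}
#'   \item{`backbone`}{shorthand for `name N CA C O`}
#'   \item{`all`}{every atom}
#' }
#' Resolution is deterministic and returns indices in topology order.
#'
#' @param topology an [md_structure] (or [md_trajectory], whose topology is
#'   used)
#' @param expression selection string
#' @return an `md_selection`: list with `expression` and ordered 1-based
#'   `indices` into the atom table
#' @examples
#' s <- build_ideal_helix(10)
#' resolve_selection(s, "backbone")
#' @export
resolve_selection <- function(topology, expression) {
  if (inherits(topology, "md_trajectory")) topology <- topology$topology
  stopifnot(inherits(topology, "md_structure"))
  at <- topology$atoms
  toks <- .sel_tokenize(expression)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  mask <- .sel_expr(st, at)
  if (st$pos <= length(st$toks))
    stop("selection syntax error near '", st$toks[st$pos], "' in: ",
         expression)
  idx <- which(mask)
  if (!length(idx))
    stop("empty selection: '", expression, "' matches no atoms")
  structure(list(expression = expression, indices = idx),
            class = "md_selection")
}

#' @export
print.md_selection <- function(x, ...) {
  cat("md_selection: '", x$expression, "' -> ", length(x$indices),
      " atoms\n", sep = "")
  invisible(x)
}

.sel_tokenize <- function(expression) {
  if (!is.character(expression) || length(expression) != 1 ||
      !nzchar(trimws(expression)))
    stop("selection expression must be a non-empty string")
  x <- gsub("\\(", " ( ", expression)
  x <- gsub("\\)", " ) ", x)
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  toks
}

.sel_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA
.sel_next <- function(st) { t <- .sel_peek(st); st$pos <- st$pos + 1L; t }

.sel_expr <- function(st, at) {          # term (or term)*
  m <- .sel_term(st, at)
  while (!is.na(.sel_peek(st)) && tolower(.sel_peek(st)) == "or") {
    .sel_next(st)
    m <- m | .sel_term(st, at)
  }
  m
}

.sel_term <- function(st, at) {          # factor (and factor)*
  m <- .sel_factor(st, at)
  while (!is.na(.sel_peek(st)) && tolower(.sel_peek(st)) == "and") {
    .sel_next(st)
    m <- m & .sel_factor(st, at)
  }
  m
}

.sel_factor <- function(st, at) {
  tok <- .sel_peek(st)
  if (is.na(tok)) stop("selection syntax error: unexpected end of expression")
  if (tok == "(") {
    .sel_next(st)
    m <- .sel_expr(st, at)
    if (is.na(.sel_peek(st)) || .sel_next(st) != ")")
      stop("selection syntax error: unbalanced parenthesis")
    return(m)
  }
  .sel_clause(st, at)
}

.sel_is_arg <- function(tok) {
  !is.na(tok) && !(tolower(tok) %in% c("and", "or")) && !(tok %in% c("(", ")"))
}

.sel_clause <- function(st, at) {
  kw <- tolower(.sel_next(st))
  switch(kw,
    all = rep(TRUE, nrow(at)),
    backbone = at$atom_name %in% c("N", "CA", "C", "O"),
    chain = {
      args <- character()
      while (.sel_is_arg(.sel_peek(st))) args <- c(args, .sel_next(st))
      if (!length(args)) stop("selection syntax error: 'chain' needs an id")
      at$chain_id %in% args
    },
    name = {
      args <- character()
      while (.sel_is_arg(.sel_peek(st))) args <- c(args, .sel_next(st))
      if (!length(args)) stop("selection syntax error: 'name' needs atom names")
      at$atom_name %in% toupper(args)
    },
    resid = {
      args <- character()
      while (.sel_is_arg(.sel_peek(st))) args <- c(args, .sel_next(st))
      if (!length(args))
        stop("selection syntax error: 'resid' needs residue numbers")
      wanted <- integer()
      for (a in args) {
        if (grepl("^-?[0-9]+--?[0-9]+$", a)) {
          parts <- regmatches(a, regexec("^(-?[0-9]+)-(-?[0-9]+)$", a))[[1]]
          wanted <- c(wanted, seq(as.integer(parts[2]), as.integer(parts[3])))
        } else if (grepl("^-?[0-9]+$", a)) {
          wanted <- c(wanted, as.integer(a))
        } else stop("selection syntax error: bad residue token '", a, "'")
      }
      at$residue_index %in% wanted
    },
    stop("selection syntax error: unknown keyword '", kw, "'")
  )
}

# subset a structure/trajectory to a selection (atom order preserved)
.sel_xyz <- function(obj, sel) {
  if (inherits(obj, "md_structure")) obj$xyz[sel$indices, , drop = FALSE]
  else obj$frames[sel$indices, , , drop = FALSE]
}
.sel_atoms <- function(obj, sel) {
  at <- if (inherits(obj, "md_structure")) obj$atoms else obj$topology$atoms
  at[sel$indices, , drop = FALSE]
}
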