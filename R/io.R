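#' Read a Bayesian network from a BIF file
#'
#' Parses the JavaBayes/bnlearn "network / variable / probability" BIF
#' dialect: discrete variables only, probability blocks either as labelled
#' per-parent-configuration rows `(state, ...) p1, p2, ...;` or as a flat
#' `table ...;` listing.  Parsing is whitespace-insensitive and names are
#' case-sensitive.
#'
#' In a `table` listing the values are laid out over `(variable, parents in
#' declared order)` with the last listed variable varying fastest (so for a
#' conditional CPT the variable itself varies slowest), matching the usual
#' BIF writers; in a labelled row the values run over the variable's states.
#'
#' @param path file path.
#' @param strict logical; if `TRUE`, CPT rows deviating from sum 1 by more
#'   than 1e-6 are an error, otherwise a warning.
#' @return a `bn` object.
#' @export
read_bif <- function(path, strict = FALSE) {
  if (!file.exists(path))
    stop(errorCondition(sprintf("file not found: %s", path),
                        class = c("klbn_parse_error", "error", "condition")))
  toks <- bif_tokenize(readLines(path, warn = FALSE))
  cur <- new.env(parent = emptyenv())
  cur$i <- 1L
  cur$toks <- toks
  states <- list()
  parents <- list()
  cpts <- list()
  while (cur$i <= nrow(cur$toks)) {
    kw <- tk_next(cur)
    if (kw == "network") {
      tk_next(cur)                       # network name
      tk_skip_block(cur)
    } else if (kw == "variable") {
      v <- tk_next(cur)
      if (v %in% names(states))
        bif_stop(cur, sprintf("duplicate variable '%s'", v))
      tk_expect(cur, "{")
      tk_expect(cur, "type"); tk_expect(cur, "discrete")
      tk_expect(cur, "["); n <- as.integer(tk_next(cur)); tk_expect(cur, "]")
      tk_expect(cur, "{")
      st <- character()
      repeat {
        tok <- tk_next(cur)
        if (tok == "}") break
        if (tok != ",") st <- c(st, tok)
      }
      tk_expect(cur, ";")
      tk_expect(cur, "}")
      if (length(st) != n)
        bif_stop(cur, sprintf("variable '%s' declares %d states but lists %d",
                              v, n, length(st)))
      states[[v]] <- st
    } else if (kw == "probability") {
      tk_expect(cur, "(")
      child <- tk_next(cur)
      pa <- character()
      tok <- tk_next(cur)
      if (tok == "|") {
        repeat {
          pa <- c(pa, tk_next(cur))
          tok <- tk_next(cur)
          if (tok == ")") break
          if (tok != ",") bif_stop(cur, "malformed probability header")
        }
      } else if (tok != ")") bif_stop(cur, "malformed probability header")
      fam <- c(child, pa)
      miss <- setdiff(fam, names(states))
      if (length(miss))
        bif_stop(cur, sprintf("undeclared variable(s): %s",
                              paste(miss, collapse = ", ")))
      parents[[child]] <- pa
      cpts[[child]] <- bif_read_table(cur, child, pa, states)
    } else {
      bif_stop(cur, sprintf("unexpected token '%s'", kw))
    }
  }
  miss <- setdiff(names(states), names(cpts))
  if (length(miss))
    stop(errorCondition(
      sprintf("no probability block for: %s", paste(miss, collapse = ", ")),
      class = c("klbn_parse_error", "error", "condition")))
  bayesian_network(states, parents, cpts, strict = strict)
}

bif_tokenize <- function(lines) {
  text <- paste(lines, collapse = "\n")
  text <- gsub("(?s)/\\*.*?\\*/", " ", text, perl = TRUE)
  lines <- sub("//.*$", "", strsplit(text, "\n", fixed = TRUE)[[1]])
  pat <- "\"[^\"]*\"|[A-Za-z0-9_.+-]+|[{}()\\[\\];|,=]"
  tok <- character(); line <- integer()
  for (i in seq_along(lines)) {
    m <- regmatches(lines[[i]], gregexpr(pat, lines[[i]], perl = TRUE))[[1]]
    if (length(m)) {
      tok <- c(tok, gsub("^\"|\"$", "", m))
      line <- c(line, rep.int(i, length(m)))
    }
  }
  data.frame(tok = tok, line = line, stringsAsFactors = FALSE)
}

tk_next <- function(cur) {
  if (cur$i > nrow(cur$toks)) bif_stop(cur, "unexpected end of file")
  tok <- cur$toks$tok[[cur$i]]
  cur$i <- cur$i + 1L
  tok
}

tk_expect <- function(cur, what) {
  tok <- tk_next(cur)
  if (tok != what)
    bif_stop(cur, sprintf("expected '%s', found '%s'", what, tok))
  tok
}

tk_skip_block <- function(cur) {
  tk_expect(cur, "{")
  depth <- 1L
  while (depth > 0L) {
    tok <- tk_next(cur)
    if (tok == "{") depth <- depth + 1L
    if (tok == "}") depth <- depth - 1L
  }
}

bif_stop <- function(cur, msg) {
  ln <- if (cur$i <= nrow(cur$toks)) cur$toks$line[[cur$i]]
        else cur$toks$line[[nrow(cur$toks)]]
  stop(errorCondition(sprintf("BIF parse error near line %d: %s", ln, msg),
                      class = c("klbn_parse_error", "error", "condition")))
}

bif_read_table <- function(cur, child, pa, states) {
  nc <- length(states[[child]])
  pcard <- vapply(states[pa], length, integer(1))
  arr <- array(NA_real_, dim = c(nc, pcard))
  tk_expect(cur, "{")
  repeat {
    tok <- tk_next(cur)
    if (tok == "}") break
    if (tok == "table") {
      vals <- bif_read_numbers(cur)
      if (length(vals) != nc * prod(pcard))
        bif_stop(cur, sprintf("table for '%s' has %d values, expected %d",
                              child, length(vals), nc * prod(pcard)))
      # last declared variable varies fastest: reverse dims, then permute
      a <- array(vals, dim = rev(c(nc, pcard)))
      arr <- aperm(a, rev(seq_along(dim(a))))
    } else if (tok == "(") {
      cfg <- integer()
      j <- 0L
      repeat {
        lab <- tk_next(cur)
        if (lab == ")") break
        if (lab == ",") next
        j <- j + 1L
        if (j > length(pa)) bif_stop(cur, "too many states in row label")
        k <- match(lab, states[[pa[[j]]]])
        if (is.na(k))
          bif_stop(cur, sprintf("unknown state '%s' of '%s'", lab, pa[[j]]))
        cfg <- c(cfg, k)
      }
      if (j != length(pa)) bif_stop(cur, "too few states in row label")
      vals <- bif_read_numbers(cur)
      if (length(vals) != nc)
        bif_stop(cur, sprintf("row for '%s' has %d values, expected %d",
                              child, length(vals), nc))
      ix <- c(list(seq_len(nc)), as.list(cfg))
      arr <- do.call(`[<-`, c(list(arr), ix, list(value = vals)))
    } else {
      bif_stop(cur, sprintf("unexpected token '%s' in probability block", tok))
    }
  }
  if (anyNA(arr))
    bif_stop(cur, sprintf("probability block for '%s' is incomplete", child))
  as.numeric(arr)
}

bif_read_numbers <- function(cur) {
  vals <- numeric()
  repeat {
    tok <- tk_next(cur)
    if (tok == ";") break
    if (tok == ",") next
    x <- suppressWarnings(as.numeric(tok))
    if (is.na(x)) bif_stop(cur, sprintf("expected a number, found '%s'", tok))
    vals <- c(vals, x)
  }
  vals
}

#' Write a Bayesian network to a BIF file
#'
#' Emits the JavaBayes/bnlearn dialect: a `table` listing for root variables
#' and labelled per-parent-configuration rows otherwise.  Parameters are
#' printed with 17 significant digits so that a write/read round trip
#' reproduces the network exactly (KL of 0 against the original); output is
#' byte-identical across runs for a fixed network.
#'
#' @param net a `bn` object.
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_bif <- function(net, path) {
  fmt <- function(x) vapply(x, function(v) sprintf("%.17g", v), character(1))
  out <- c("network unknown {", "}")
  for (v in net$vars) {
    st <- net$states[[v]]
    out <- c(out,
             sprintf("variable %s {", v),
             sprintf("  type discrete [ %d ] { %s };", length(st),
                     paste(st, collapse = ", ")),
             "}")
  }
  for (v in net$vars) {
    pa <- net$parents[[v]]
    cp <- net$cpts[[v]]
    if (!length(pa)) {
      vals <- vapply(seq_along(net$states[[v]]), function(k)
        pot_value(cp, stats::setNames(k, v)), numeric(1))
      out <- c(out,
               sprintf("probability ( %s ) {", v),
               sprintf("  table %s;", paste(fmt(vals), collapse = ", ")),
               "}")
    } else {
      out <- c(out, sprintf("probability ( %s | %s ) {", v,
                            paste(pa, collapse = ", ")))
      grid <- config_grid(vapply(net$states[pa], length, integer(1)))
      for (r in seq_len(nrow(grid))) {
        cfg <- stats::setNames(as.integer(grid[r, ]), pa)
        labs <- vapply(pa, function(p) net$states[[p]][[cfg[[p]]]],
                       character(1))
        row <- pot_restrict(cp, cfg)
        vals <- vapply(seq_along(net$states[[v]]), function(k)
          pot_value(row, stats::setNames(k, v)), numeric(1))
        out <- c(out, sprintf("  (%s) %s;", paste(labs, collapse = ", "),
                              paste(fmt(vals), collapse = ", ")))
      }
      out <- c(out, "}")
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read / write the JSON network dialect
#'
#' A small JSON representation used for tests and interchange: `variables`
#' (name + states, in declaration order), `parents`, and `cpts` with each
#' table flattened over `(variable, parents in listed order)`, the variable
#' itself varying fastest.
#'
#' @param path file path.
#' @param strict passed to [bayesian_network()].
#' @return `read_bn_json` returns a `bn`; `write_bn_json` returns `path`
#'   invisibly.
#' @export
read_bn_json <- function(path, strict = FALSE) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop(errorCondition(
                    sprintf("JSON parse error: %s", conditionMessage(e)),
                    class = c("klbn_parse_error", "error", "condition"))))
  vars <- vapply(doc$variables, function(v) v$name, character(1))
  states <- stats::setNames(
    lapply(doc$variables, function(v) as.character(unlist(v$states))), vars)
  parents <- lapply(doc$parents, function(p) as.character(unlist(p)))
  cpts <- lapply(doc$cpts, function(x) as.numeric(unlist(x)))
  bayesian_network(states, parents, cpts, strict = strict)
}

#' @rdname read_bn_json
#' @param net a `bn` object.
#' @export
write_bn_json <- function(net, path) {
  cpts <- lapply(net$vars, function(v) {
    pa <- net$parents[[v]]
    fam <- c(v, pa)
    grid <- config_grid(vapply(net$states[fam], length, integer(1)))
    vapply(seq_len(nrow(grid)), function(r)
      pot_value(net$cpts[[v]], stats::setNames(as.integer(grid[r, ]), fam)),
      numeric(1))
  })
  doc <- list(
    variables = lapply(net$vars, function(v)
      list(name = v, states = I(net$states[[v]]))),
    parents = lapply(net$parents, I),
    cpts = stats::setNames(lapply(cpts, I), net$vars))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
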