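#' Residue vocabulary used to classify tokens in CSDB linear notation
#'
#' Residue classification (monosaccharide, monovalent substituent, aglycon,
#' superclass, alias) is not derivable from a residue's spelling alone, so the
#' package ships an editable vocabulary. Any token not matched by the
#' vocabulary or by the `Subst` alias pattern is treated as a monosaccharide.
#'
#' @param monovalent Character vector of single-attachment substituent
#'   residues (acetyl, methyl, phosphate, sulfate, ...).
#' @param superclass Character vector of generic residue categories used when
#'   the exact identity is unknown (e.g. `LIP`, `HEX`).
#' @param aglycon Character vector of residue names classified as aglycons
#'   (non-carbohydrate moieties at the reducing end).
#'
#' @return A list with components `monovalent`, `superclass` and `aglycon`.
#' @export
#' @examples
#' v <- csdb_vocabulary()
#' "Ac" %in% v$monovalent
csdb_vocabulary <- function(monovalent = c("Ac", "Me", "P", "S", "EtN", "Gro",
                                           "Fo", "Am", "Gc"),
                            superclass = c("LIP", "HEX", "PEN", "HEP", "OCT",
                                           "NON", "SUG"),
                            aglycon = c("Cer", "Chol", "diosgenin",
                                        "dolichol", "phosphatidylinositol")) {
  list(monovalent = as.character(monovalent),
       superclass = as.character(superclass),
       aglycon = as.character(aglycon))
}

#' @keywords internal
.alias_pattern <- "^Subst[0-9]*$"

# ---- low-level helpers -------------------------------------------------------

csdb_error <- function(msg, offset = NA_integer_, line = NA_integer_) {
  at <- if (!is.na(offset)) sprintf(" (column %d)", offset) else ""
  ln <- if (!is.na(line)) sprintf(" [line %d]", line) else ""
  rlang::abort(paste0("CSDB notation error", ln, at, ": ", msg),
               class = "glycotaxa_parse_error",
               offset = offset, line = line)
}

# Split "anomer + rest" and "config + stem" off a monosaccharide spelling.
# The anomeric prefix is a/b/? followed by an uppercase letter or '?';
# the absolute configuration is D/L/? followed by an uppercase letter or '?'.
split_residue_spelling <- function(token) {
  anomer <- ""
  config <- ""
  rest <- token
  if (nchar(rest) > 1 &&
      substr(rest, 1, 1) %in% c("a", "b", "?") &&
      grepl("^[A-Z?]", substr(rest, 2, nchar(rest)))) {
    anomer <- substr(rest, 1, 1)
    rest <- substr(rest, 2, nchar(rest))
  }
  if (nchar(rest) > 1 &&
      substr(rest, 1, 1) %in% c("D", "L", "?") &&
      grepl("^[A-Z?]", substr(rest, 2, nchar(rest)))) {
    config <- substr(rest, 1, 1)
    rest <- substr(rest, 2, nchar(rest))
  }
  # Ring size: CSDB embeds the ring letter inside the spelling (aDGlcp,
  # bDGlcpN); extraction is best effort and only informative -- filters rely
  # on the presence of '?' and on the anomeric prefix, both exact.
  ring <- ""
  if (grepl("[pf]$", rest)) {
    ring <- substr(rest, nchar(rest), nchar(rest))
  } else if (grepl("^.{3,}[pf]", rest)) {
    ring <- sub("^.{3}.*?([pf]).*$", "\\1", rest)
  } else if (grepl("\\?$", rest)) {
    ring <- "?"
  }
  list(anomer = anomer, config = config, stem = rest, ring = ring)
}

classify_token <- function(token, vocab, alias_names = character()) {
  if (grepl(.alias_pattern, token) || token %in% alias_names) return("alias")
  if (token %in% vocab$monovalent) return("monovalent")
  if (token %in% vocab$superclass) return("superclass")
  if (token %in% vocab$aglycon) return("aglycon")
  "monosaccharide"
}

make_residue <- function(token, vocab, alias_table) {
  cls <- classify_token(token, vocab, names(alias_table))
  if (cls == "monosaccharide") {
    sp <- split_residue_spelling(token)
    list(token = token, anomer = sp$anomer, config = sp$config,
         ring = sp$ring, residue_class = cls, alias_value = NA_character_)
  } else {
    list(token = token, anomer = "", config = "", ring = "",
         residue_class = cls,
         alias_value = if (cls == "alias" && token %in% names(alias_table))
           alias_table[[token]] else NA_character_)
  }
}

#' Expand shortcut residue spellings
#'
#' CSDB shortcut forms fold a monovalent substituent into a residue spelling:
#' an N-acetylated amino sugar such as `GlcNAc` stands for `GlcN` carrying
#' `Ac` at position 2, and `-nOMe`/`-nOAc` suffixes attach a methyl or acetyl
#' group at position n (`Glc-1OMe` is the dimer `Glc(1-1)Me`). Non-shortcut
#' tokens pass through unchanged; expansion is idempotent.
#'
#' @param token A single residue token.
#' @return A list with `base` (the bare residue spelling) and `attachments`,
#'   a tibble with columns `token`, `position` and `direction` (`"donor"`
#'   when the substituent donates onto the base residue, `"acceptor"` when
#'   the base residue donates onto the substituent, as in `Glc(1-1)Me`).
#' @export
#' @examples
#' expand_shortcuts("GlcNAc")
#' expand_shortcuts("Man")
expand_shortcuts <- function(token) {
  stopifnot(is.character(token), length(token) == 1L)
  att <- tibble::tibble(token = character(), position = character(),
                        direction = character())
  base <- token
  m <- regmatches(base, regexec("^(.+)-([1-9])O(Me|Ac)$", base))[[1]]
  if (length(m)) {
    pos <- m[3]
    att <- tibble::add_row(att, token = m[4], position = pos,
                           direction = if (pos == "1") "acceptor" else "donor")
    base <- m[2]
  }
  if (grepl("NAc$", base) && nchar(base) > 3) {
    att <- tibble::add_row(att, token = "Ac", position = "2",
                           direction = "donor")
    base <- substr(base, 1, nchar(base) - 2)
  }
  if (grepl("(NAc$)|(-[1-9]O(Me|Ac)$)", base))
    csdb_error(paste0("unsupported shortcut suffix in '", token, "'"))
  list(base = base, attachments = att)
}

# ---- tokenizer ---------------------------------------------------------------

.POS_CHARS <- c(as.character(1:9), "?")

tokenize_csdb <- function(body, line = NA_integer_) {
  toks <- list()
  push <- function(kind, at, ...) {
    toks[[length(toks) + 1L]] <<- c(list(kind = kind, at = at), list(...))
  }
  n <- nchar(body)
  i <- 1L
  ch <- function(k) substr(body, k, k)

  # polymer opening "-n)"
  if (n >= 3L && ch(1L) == "-" && ch(2L) %in% .POS_CHARS && ch(3L) == ")") {
    push("POLY_OPEN", 1L, pos = ch(2L))
    i <- 4L
  }
  while (i <= n) {
    c0 <- ch(i)
    if (c0 == "[") { push("LBRACKET", i); i <- i + 1L; next }
    if (c0 == "]") { push("RBRACKET", i); i <- i + 1L; next }
    if (c0 == "(") {
      if (i + 1L <= n && ch(i + 1L) %in% .POS_CHARS && ch(i + 2L) == "-") {
        if (i + 3L <= n && ch(i + 3L) %in% .POS_CHARS && ch(i + 4L) == ")") {
          push("LINK", i, dpos = ch(i + 1L), apos = ch(i + 3L))
          i <- i + 5L
          next
        }
        if (i + 2L == n) {                      # "(m-" polymer closure
          push("POLY_CLOSE", i, pos = ch(i + 1L))
          i <- i + 3L
          next
        }
      }
      csdb_error("malformed linkage", offset = i, line = line)
    }
    if (c0 == ")") csdb_error("unexpected ')'", offset = i, line = line)
    # residue token: consume up to a structural character; a '-' starts a
    # short-form linkage "-n)" only when followed by a position and ')'
    start <- i
    while (i <= n) {
      ci <- ch(i)
      if (ci %in% c("(", "[", "]")) break
      if (ci == "-" && i + 2L <= n && ch(i + 1L) %in% .POS_CHARS &&
          ch(i + 2L) == ")") break
      i <- i + 1L
    }
    token <- substr(body, start, i - 1L)
    if (!nchar(token)) csdb_error("empty residue token", offset = start, line = line)
    push("RES", start, token = trimws(token))
    if (i <= n && ch(i) == "-") {               # short-form donor linkage
      push("LINK", i, dpos = NA_character_, apos = ch(i + 1L))
      i <- i + 3L
    }
  }
  toks
}

# ---- parser ------------------------------------------------------------------

#' Parse a structure in CSDB linear notation
#'
#' Parses one oligomer or polymer repeating unit into a rooted
#' residue/linkage graph. The rightmost residue of the main chain is the root
#' (reducing end or aglycon); branches in `[...]` immediately precede their
#' acceptor; a repeating unit opens with `-n)` and closes with `(m-`, joined
#' by a wrap-around linkage; alias declarations follow `//` as
#' `Name = free text`, separated by `;`. Shortcut spellings are expanded (see
#' [expand_shortcuts()]).
#'
#' @param text A single line of CSDB linear notation.
#' @param vocab Residue vocabulary, see [csdb_vocabulary()].
#' @param strict If `TRUE`, an alias residue (`Subst...`) used in the
#'   structure without a trailing `// Subst... = ...` declaration is an error.
#' @param line Optional line number used in error messages.
#'
#' @return An object of class `glycan_graph`: a list with `residues`
#'   (tibble: `token`, `anomer`, `config`, `ring`, `residue_class`,
#'   `alias_value`), `edges` (tibble: `donor`, `donor_pos`, `acceptor_pos`,
#'   `acceptor`, `wrap`; positions are characters `"1"`..`"9"`, `"?"`, or
#'   `NA` for single-attachment-center donors), `root` (residue index),
#'   `topology_kind` (`"oligomer"` or `"polymer_repeat"`) and `alias_table`.
#' @export
#' @examples
#' g <- parse_csdb("Gal(1-3)GlcNAc(1-2)Man")
#' nrow(g$residues)  # 4: Gal, GlcN, Ac, Man
#' nrow(g$edges)     # 3
parse_csdb <- function(text, vocab = csdb_vocabulary(), strict = TRUE,
                       line = NA_integer_) {
  stopifnot(is.character(text), length(text) == 1L)
  parts <- strsplit(text, "//", fixed = TRUE)[[1]]
  if (!length(parts)) csdb_error("empty structure", line = line)
  if (length(parts) > 2L)
    csdb_error("more than one '//' alias block", line = line)
  body <- trimws(parts[1])
  if (!nchar(body)) csdb_error("empty structure", line = line)
  if (grepl("\\s", body))
    csdb_error(paste0("whitespace inside a structure body; multiple ",
                      "structures per line are not supported"), line = line)

  alias_table <- character()
  if (length(parts) == 2L) {
    decls <- strsplit(parts[2], ";", fixed = TRUE)[[1]]
    for (d in decls) {
      d <- trimws(d)
      if (!nchar(d)) next
      kv <- regmatches(d, regexec("^([^=]+?)\\s*=\\s*(.+)$", d))[[1]]
      if (!length(kv)) csdb_error(paste0("malformed alias declaration '", d, "'"),
                                  line = line)
      alias_table[[trimws(kv[2])]] <- trimws(kv[3])
    }
  }

  toks <- tokenize_csdb(body, line = line)
  kinds <- vapply(toks, function(t) t$kind, character(1))
  is_poly <- length(kinds) && kinds[1] == "POLY_OPEN"
  if ("POLY_CLOSE" %in% kinds && !is_poly)
    csdb_error("polymer closure '(m-' without opening '-n)'", line = line)
  if (is_poly && kinds[length(kinds)] != "POLY_CLOSE")
    csdb_error("polymer opening '-n)' without closing '(m-'", line = line)

  res_rows <- list()
  edge_rows <- list()
  push_residue <- function(token) {
    res_rows[[length(res_rows) + 1L]] <<- make_residue(token, vocab,
                                                       alias_table)
    length(res_rows)
  }
  push_edge <- function(donor, donor_pos, acceptor_pos, acceptor,
                        wrap = FALSE) {
    edge_rows[[length(edge_rows) + 1L]] <<-
      list(donor = donor, donor_pos = donor_pos,
           acceptor_pos = acceptor_pos, acceptor = acceptor, wrap = wrap)
  }

  add_node <- function(token, at) {
    if (grepl(.alias_pattern, token) && strict &&
        !(token %in% names(alias_table)))
      csdb_error(paste0("undeclared alias '", token, "'"), offset = at,
                 line = line)
    ex <- expand_shortcuts(token)
    base_idx <- push_residue(ex$base)
    tail_idx <- base_idx
    if (nrow(ex$attachments)) {
      for (k in seq_len(nrow(ex$attachments))) {
        a <- ex$attachments[k, ]
        sub_idx <- push_residue(a$token)
        if (a$direction == "donor") {
          push_edge(sub_idx, "1", a$position, base_idx)
        } else {
          # the substituent (methyl glycoside) becomes the local reducing end
          push_edge(base_idx, "1", a$position, sub_idx)
          tail_idx <- sub_idx
        }
      }
    }
    list(base = base_idx, tail = tail_idx)
  }

  pos <- if (is_poly) 2L else 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]]$kind else "EOF"
  take <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }

  # element := branch* RES ; returns node indices (base carries links left,
  # tail is the rightmost node after acceptor-side shortcut expansion)
  parse_element <- function() {
    branches <- list()
    while (peek() == "LBRACKET") {
      lb <- take()
      br <- parse_chain(in_branch = TRUE)
      if (is.null(br$dangling))
        csdb_error("branch must end with a linkage", offset = lb$at, line = line)
      if (peek() != "RBRACKET")
        csdb_error("unbalanced brackets", offset = lb$at, line = line)
      take()
      branches[[length(branches) + 1L]] <- br
    }
    if (peek() != "RES") {
      t <- if (pos <= length(toks)) toks[[pos]] else list(at = nchar(body))
      csdb_error("expected residue", offset = t$at, line = line)
    }
    t <- take()
    nd <- add_node(t$token, t$at)
    for (br in branches) {
      push_edge(br$tip, br$dangling$dpos, br$dangling$apos, nd$base)
    }
    nd
  }

  # chain := element (LINK element)* [LINK]    (the trailing LINK dangles)
  parse_chain <- function(in_branch = FALSE) {
    first <- parse_element()
    cur <- first
    dangling <- NULL
    tip <- cur$base
    repeat {
      if (peek() != "LINK") break
      lk <- take()
      nxt_kind <- peek()
      if (nxt_kind %in% c("RES", "LBRACKET")) {
        nxt <- parse_element()
        push_edge(cur$tail, lk$dpos, lk$apos, nxt$base)
        cur <- nxt
      } else {
        dangling <- lk
        break
      }
    }
    list(first = first$base, tip = cur$tail, dangling = dangling)
  }

  main <- parse_chain()
  if (peek() == "POLY_CLOSE") {
    pc <- take()
    push_edge(main$tip, pc$pos, toks[[1]]$pos, main$first, wrap = TRUE)
  } else if (!is.null(main$dangling)) {
    csdb_error("dangling linkage at end of structure",
               offset = main$dangling$at, line = line)
  }
  if (peek() != "EOF") {
    t <- toks[[pos]]
    csdb_error(paste0("unexpected ", tolower(t$kind)), offset = t$at,
               line = line)
  }

  field <- function(rows, name, cast) cast(vapply(rows, `[[`, cast(NA), name))
  residues <- tibble::tibble(
    token = field(res_rows, "token", as.character),
    anomer = field(res_rows, "anomer", as.character),
    config = field(res_rows, "config", as.character),
    ring = field(res_rows, "ring", as.character),
    residue_class = field(res_rows, "residue_class", as.character),
    alias_value = field(res_rows, "alias_value", as.character))
  edges <- tibble::tibble(
    donor = field(edge_rows, "donor", as.integer),
    donor_pos = field(edge_rows, "donor_pos", as.character),
    acceptor_pos = field(edge_rows, "acceptor_pos", as.character),
    acceptor = field(edge_rows, "acceptor", as.integer),
    wrap = field(edge_rows, "wrap", as.logical))
  structure(list(residues = residues, edges = edges, root = main$tip,
                 topology_kind = if (is_poly) "polymer_repeat" else "oligomer",
                 alias_table = alias_table),
            class = "glycan_graph")
}

#' @export
print.glycan_graph <- function(x, ...) {
  cat(sprintf("<glycan_graph: %d residues, %d linkages, %s, root %s>\n",
              nrow(x$residues), nrow(x$edges), x$topology_kind,
              x$residues$token[x$root]))
  invisible(x)
}

# incoming (substituent) edges of a node, excluding the wrap-around linkage
incoming_edges <- function(graph, node) {
  dplyr::filter(graph$edges, .data$acceptor == node, !.data$wrap)
}

link_text <- function(dpos, apos) {
  if (is.na(dpos)) paste0("-", apos, ")") else paste0("(", dpos, "-", apos, ")")
}

#' Serialize a glycan graph back to CSDB linear notation
#'
#' Produces a canonical spelling: at every residue the unbracketed main chain
#' continues into the lexicographically smallest rendered subtree (for a
#' repeating unit, into the subtree holding the wrap-around acceptor), and
#' remaining substituents appear as sorted `[...]` branches. Because the
#' rendering is canonical, two graphs are isomorphic exactly when their
#' serializations are equal, and `parse_csdb(serialize_csdb(g))` reproduces
#' `g` up to residue ordering.
#'
#' @param graph A `glycan_graph`.
#' @return A single character string.
#' @export
#' @examples
#' serialize_csdb(parse_csdb("aDManp"))
serialize_csdb <- function(graph) {
  stopifnot(inherits(graph, "glycan_graph"))
  wrap <- dplyr::filter(graph$edges, .data$wrap)
  spine_target <- if (nrow(wrap)) wrap$acceptor[1] else NA_integer_

  contains <- function(node, target) {
    if (is.na(target)) return(FALSE)
    if (node == target) return(TRUE)
    inc <- incoming_edges(graph, node)
    any(vapply(inc$donor, contains, logical(1), target = target))
  }

  render <- function(node, on_spine) {
    inc <- incoming_edges(graph, node)
    token <- graph$residues$token[node]
    if (!nrow(inc)) return(token)
    parts <- vapply(seq_len(nrow(inc)), function(k) {
      paste0(render(inc$donor[k], FALSE),
             link_text(inc$donor_pos[k], inc$acceptor_pos[k]))
    }, character(1))
    main_k <- if (on_spine && !is.na(spine_target) && node != spine_target) {
      kk <- which(vapply(inc$donor, contains, logical(1),
                         target = spine_target))
      kk[1]
    } else if (on_spine && !is.na(spine_target) && node == spine_target) {
      NA_integer_  # wrap acceptor: everything bracketed, it stays leftmost
    } else {
      order(parts)[1]
    }
    bracketed <- function(v) {
      if (length(v)) paste0("[", v, "]", collapse = "") else ""
    }
    if (is.na(main_k)) {
      paste0(bracketed(sort(parts)), token)
    } else {
      rest <- sort(parts[-main_k])
      # re-render main child along the spine so the wrap acceptor stays left
      main_txt <- paste0(render(inc$donor[main_k], on_spine),
                         link_text(inc$donor_pos[main_k],
                                   inc$acceptor_pos[main_k]))
      paste0(main_txt, bracketed(rest), token)
    }
  }

  body <- render(graph$root, on_spine = nrow(wrap) > 0)
  if (nrow(wrap))
    body <- paste0("-", wrap$acceptor_pos[1], ")", body, "(",
                   wrap$donor_pos[1], "-")
  if (length(graph$alias_table)) {
    decls <- paste(names(graph$alias_table), "=", unname(graph$alias_table))
    body <- paste0(body, " // ", paste(decls, collapse = "; "))
  }
  body
}

#' Test whether two glycan graphs are isomorphic
#'
#' Compares the canonical serializations of the two graphs (ignoring alias
#' declarations), so residue numbering and branch order do not matter.
#'
#' @param a,b `glycan_graph` objects.
#' @return `TRUE` or `FALSE`.
#' @export
graph_isomorphic <- function(a, b) {
  strip <- function(g) { g$alias_table <- character(); serialize_csdb(g) }
  identical(strip(a), strip(b))
}
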