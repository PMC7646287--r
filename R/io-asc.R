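# Neurolucida-style ASC writer and reader.
#
# Dialect written here (and accepted back, superset-tolerantly):
#   - one ("CellBody" ...) block per soma contour, points as (x y z d);
#   - one parenthesized tree per neurite with an (Axon)/(Dendrite)/(Apical)
#     header, points as (x y z d) with d = 2 * radius, sibling branches
#     inside a ( ... | ... ) group, terminals ended by the keyword Normal;
#   - spine markers as `<(x y z d)> ; Spine` lines immediately after their
#     insertion point's line (the insertion point of a spine is the
#     preceding point within the tracing).
# Coordinates use fixed 2-decimal formatting.

part_to_asc <- function(part) {
  switch(part, axon = "Axon", apical = "Apical", "Dendrite")
}

asc_to_part <- function(label) {
  switch(label, Axon = "axon", Apical = "apical", Dendrite = "basal",
         "basal")
}

fmt_pt <- function(x, y, z, d) sprintf("(%.2f %.2f %.2f %.2f)", x, y, z, d)

#' Write a tracing to an ASC file
#'
#' Emits the contour-soma, neurite-tree and spine-marker dialect described
#' in the package's format notes. Spine markers are written immediately
#' after the line of their insertion point (set `spine_markers_after =
#' FALSE` to emit them before it instead).
#'
#' @param t a valid [neuron_tracing()].
#' @param path output path.
#' @param n_soma_contours contour count used when the soma model must be
#'   converted to contours first.
#' @param spine_markers_after place each spine marker after (default) or
#'   before its insertion point's line.
#' @return `path`, invisibly.
#' @export
write_asc <- function(t, path, n_soma_contours = 7,
                      spine_markers_after = TRUE) {
  viol <- validate_tracing(t)
  if (nrow(viol))
    stop_neurofil(paste0("invalid tracing: ", viol$rule[1]),
                  "neurofil_invalid_tracing")
  out <- character(0)
  emit <- function(...) out <<- c(out, paste0(...))
  if (!is.null(t$soma)) {
    cs <- if (t$soma$variant == "contour_stack") t$soma$contours
    else soma_to_contours(t$soma, n_levels = n_soma_contours)
    for (cc in cs$contours) {
      emit("(\"CellBody\"")
      emit(" (CellBody)")
      d <- 0 # contour points carry no thickness
      for (i in seq_len(nrow(cc)))
        emit(" ", fmt_pt(cc[i, 1], cc[i, 2], cc[i, 3], d))
      emit(")")
    }
  }
  nd <- t$nodes
  kids <- split(nd$id, factor(nd$parent, levels = c(0, nd$id)))
  spines_at <- split(seq_len(nrow(t$spines)), t$spines$parent_id)
  point_line <- function(id, indent) {
    row <- match(id, nd$id)
    lines <- fmt_pt(nd$x[row], nd$y[row], nd$z[row], 2 * nd$radius[row])
    marker <- character(0)
    for (s in spines_at[[as.character(id)]])
      marker <- c(marker, sprintf("<(%.2f %.2f %.2f %.2f)> ; Spine",
                                  t$spines$x[s], t$spines$y[s],
                                  t$spines$z[s], 2 * t$spines$radius[s]))
    pad <- strrep(" ", indent)
    if (spine_markers_after) paste0(pad, c(lines, marker))
    else paste0(pad, c(marker, lines))
  }
  emit_subtree <- function(id, indent) {
    repeat {
      out <<- c(out, point_line(id, indent))
      ch <- kids[[as.character(id)]]
      if (length(ch) == 0) {
        emit(strrep(" ", indent), "Normal")
        return()
      }
      if (length(ch) == 1) { id <- ch; next }
      emit(strrep(" ", indent), "(")
      for (k in seq_along(ch)) {
        if (k > 1) emit(strrep(" ", indent), "|")
        emit_subtree(ch[k], indent + 2)
      }
      emit(strrep(" ", indent), ")")
      return()
    }
  }
  for (root in nd$id[nd$parent == 0]) {
    row <- match(root, nd$id)
    emit("( (", part_to_asc(nd$part[row]), ")")
    emit_subtree(root, 2)
    emit(")")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read an ASC file
#'
#' Parses the dialect written by [write_asc()], tolerating unknown markers
#' (ignored with a warning). Coordinates come back at the written 0.01
#' precision; topology and part labels are exact, so
#' `read_asc(write_asc(t))` preserves the tree structure of `t`.
#'
#' @param path an `.asc` file.
#' @return a [neuron_tracing()] (soma as a contour-stack model when
#'   CellBody blocks are present).
#' @export
read_asc <- function(path) {
  txt <- readLines(path, warn = FALSE)
  toks <- asc_tokenize(txt)
  pos <- 1L
  peek <- function() if (pos <= length(toks$type)) toks$type[pos] else "eof"
  val <- function() toks$value[[pos]]
  advance <- function() pos <<- pos + 1L
  expect <- function(tp) {
    if (peek() != tp)
      stop_neurofil(sprintf("ASC parse error near line %d: expected %s, got %s",
                            toks$line[min(pos, length(toks$line))], tp, peek()),
                    "neurofil_parse_error")
    v <- val(); advance(); v
  }
  contours <- list()
  nodes <- empty_nodes()
  spines <- empty_spines()
  next_id <- 0L
  unknown_markers <- 0L

  read_point <- function() {
    expect("open")
    nums <- numeric(0)
    while (peek() == "number") { nums <- c(nums, as.numeric(val())); advance() }
    expect("close")
    if (length(nums) < 3)
      stop_neurofil("ASC point with fewer than 3 coordinates",
                    "neurofil_parse_error")
    if (length(nums) < 4) nums[4] <- 0
    nums[1:4]
  }
  # a parenthesized neurite body: points, optional markers, branch groups
  read_tree <- function(parent, part) {
    last <- parent
    repeat {
      tp <- peek()
      if (tp == "open") {
        # lookahead: point or branch group?
        if (pos + 1L <= length(toks$type) && toks$type[pos + 1L] == "number") {
          p <- read_point()
          next_id <<- next_id + 1L
          nodes <<- rbind(nodes, data.frame(
            id = next_id, parent = last, x = p[1], y = p[2], z = p[3],
            radius = p[4] / 2, part = part, stringsAsFactors = FALSE))
          last <- next_id
        } else {
          advance() # consume the branch-group "("
          repeat {
            read_tree(last, part)
            if (peek() == "pipe") { advance(); next }
            break
          }
          expect("close")
          return(invisible(NULL))
        }
      } else if (tp == "marker") {
        mk <- val(); advance()
        if (identical(mk$label, "Spine")) {
          p <- mk$point
          spines <<- rbind(spines, data.frame(
            x = p[1], y = p[2], z = p[3], radius = p[4] / 2,
            parent_id = if (last > 0) last else NA_integer_))
        } else unknown_markers <<- unknown_markers + 1L
      } else if (tp == "word" && val() == "Normal") {
        advance()
        return(invisible(NULL))
      } else if (tp == "word") {
        advance() # unknown keyword inside a tree: ignore
      } else {
        return(invisible(NULL))
      }
    }
  }

  while (peek() != "eof") {
    if (peek() != "open") { advance(); next }
    advance()
    if (peek() == "string" && val() == "CellBody") {
      advance()
      pts <- list()
      repeat {
        tp <- peek()
        if (tp == "open" && pos + 1L <= length(toks$type) &&
            toks$type[pos + 1L] == "number") {
          p <- read_point()
          pts[[length(pts) + 1]] <- p[1:3]
        } else if (tp == "open") { # nested label like (CellBody)
          advance()
          while (peek() %in% c("word", "string", "number")) advance()
          expect("close")
        } else if (tp == "word" || tp == "string") advance()
        else break
      }
      expect("close")
      if (length(pts) >= 3)
        contours[[length(contours) + 1]] <- do.call(rbind, pts)
    } else if (peek() == "open") {
      # neurite header ( (Dendrite) ... )
      advance()
      label <- if (peek() %in% c("word", "string")) { l <- val(); advance(); l }
      else "Dendrite"
      while (peek() %in% c("word", "string", "number")) advance()
      expect("close")
      read_tree(0L, asc_to_part(label))
      expect("close")
    } else {
      # unrecognised top-level block: skip to matching close
      depth <- 1L
      while (depth > 0 && peek() != "eof") {
        if (peek() == "open") depth <- depth + 1L
        if (peek() == "close") depth <- depth - 1L
        advance()
      }
    }
  }
  if (unknown_markers)
    warning(sprintf("%d unknown marker(s) ignored", unknown_markers))
  soma <- if (length(contours)) soma_contours(contour_stack(contours))
  else NULL
  spines$parent_id <- as.integer(spines$parent_id)
  neuron_tracing(nodes, soma = soma, spines = spines)
}

# tokenizer: parens, quoted strings, numbers, words, "|", and spine-style
# markers `<( x y z d )> ; Label`
asc_tokenize <- function(lines) {
  types <- character(0); values <- list(); linenos <- integer(0)
  push <- function(tp, v, ln) {
    types[[length(types) + 1]] <<- tp
    values[[length(values) + 1]] <<- v
    linenos[[length(linenos) + 1]] <<- ln
  }
  open_count <- 0L; close_count <- 0L
  for (ln in seq_along(lines)) {
    s <- lines[ln]
    # markers first (they contain parens)
    m <- regexpr("<\\(([^)]*)\\)>\\s*(;\\s*([A-Za-z0-9_]+))?", s, perl = TRUE)
    while (m != -1) {
      whole <- regmatches(s, m)
      inner <- sub(".*<\\(", "", sub("\\)>.*", "", whole))
      nums <- suppressWarnings(
        as.numeric(strsplit(trimws(inner), "[ \t]+")[[1]]))
      nums <- nums[!is.na(nums)]
      label <- sub(".*;\\s*", "", whole)
      label <- if (grepl(";", whole)) trimws(label) else ""
      push("marker", list(point = nums, label = label), ln)
      s <- sub("<\\(([^)]*)\\)>\\s*(;\\s*([A-Za-z0-9_]+))?", " ", s, perl = TRUE)
      m <- regexpr("<\\(([^)]*)\\)>\\s*(;\\s*([A-Za-z0-9_]+))?", s, perl = TRUE)
    }
    s <- sub(";.*$", "", s) # remaining comments
    pat <- "\\(|\\)|\\||\"[^\"]*\"|[-+0-9.][-+0-9.eE]*|[A-Za-z_][A-Za-z0-9_]*"
    toks_line <- regmatches(s, gregexpr(pat, s, perl = TRUE))[[1]]
    for (tok in toks_line) {
      if (tok == "(") { push("open", tok, ln); open_count <- open_count + 1L }
      else if (tok == ")") { push("close", tok, ln); close_count <- close_count + 1L }
      else if (tok == "|") push("pipe", tok, ln)
      else if (startsWith(tok, "\""))
        push("string", gsub("\"", "", tok), ln)
      else if (grepl("^[-+0-9.]", tok)) push("number", tok, ln)
      else push("word", tok, ln)
    }
  }
  if (open_count != close_count)
    stop_neurofil(sprintf("unbalanced parentheses in ASC file (%d open, %d close)",
                          open_count, close_count),
                  "neurofil_parse_error")
  list(type = as.character(types), value = values, line = as.integer(linenos))
}
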