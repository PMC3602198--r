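#' Read a constraint-based model
#'
#' Three dialects are supported. `"json"` is the canonical format: a single
#' object with `id`, `metabolites`, `reactions` (stoichiometry as a
#' metabolite->coefficient map), `genes` and `objective`. `"tsv"` is a
#' two-table convenience dialect: `path` names a directory holding
#' `metabolites.tsv` (id, name, formula, charge, compartment) and
#' `reactions.tsv` (id, name, equation, lower_bound, upper_bound, gpr,
#' subsystem, ec_numbers) where the equation is text like
#' `"2 pyr_c + 1 h_c -> 1 alac_c + 1 co2_c"`. `"sbml"` is a read-only
#' importer for an SBML Level 3 core subset with the `fbc` extension
#' (flux bounds via parameters, gene-product associations, objective).
#'
#' @param path File (json, sbml) or directory (tsv).
#' @param format `"json"`, `"tsv"` or `"sbml"`; guessed from the path when
#'   missing.
#' @return A validated [`cb_model`][new_model].
#' @export
read_model <- function(path, format = c("guess", "json", "tsv", "sbml")) {
  format <- match.arg(format)
  if (format == "guess") {
    format <- if (dir.exists(path)) "tsv"
      else if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml"
      else "json"
  }
  switch(format,
    json = read_model_json(path),
    tsv = read_model_tsv(path),
    sbml = read_model_sbml(path))
}

#' Write a constraint-based model
#'
#' @param model A `cb_model`.
#' @param path Output file (json) or directory (tsv; created if absent).
#' @param format `"json"` or `"tsv"`.
#' @return Invisibly `path`.
#' @export
write_model <- function(model, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  validate_model(model)
  if (format == "json") write_model_json(model, path)
  else write_model_tsv(model, path)
  invisible(path)
}

read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  mets <- do.call(rbind, lapply(x$metabolites, function(m) {
    data.frame(id = m$id,
               name = if (is.null(m$name)) m$id else m$name,
               formula = if (is.null(m$formula)) NA_character_ else m$formula,
               charge = if (is.null(m$charge)) NA_integer_ else as.integer(m$charge),
               compartment = m$compartment,
               stringsAsFactors = FALSE)
  }))
  rxns <- lapply(x$reactions, function(r) {
    list(id = r$id, name = r$name,
         stoichiometry = unlist(r$stoichiometry),
         lower_bound = r$lower_bound, upper_bound = r$upper_bound,
         gpr = if (is.null(r$gpr)) "" else r$gpr,
         subsystem = if (is.null(r$subsystem)) "" else r$subsystem,
         ec_numbers = as.character(unlist(r$ec_numbers)))
  })
  new_model(id = x$id, metabolites = mets, reactions = rxns,
            genes = as.character(unlist(x$genes)), objective = x$objective,
            annotations = if (is.null(x$annotations)) list() else x$annotations)
}

write_model_json <- function(model, path) {
  x <- list(
    id = model$id,
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      m <- model$metabolites[i, ]
      out <- list(id = m$id, name = m$name, compartment = m$compartment)
      if (!is.na(m$formula)) out$formula <- m$formula
      if (!is.na(m$charge)) out$charge <- m$charge
      out
    }),
    reactions = lapply(model$reactions, function(r) {
      list(id = r$id, name = r$name,
           stoichiometry = as.list(r$stoichiometry),
           lower_bound = r$lower_bound, upper_bound = r$upper_bound,
           gpr = r$gpr, subsystem = r$subsystem,
           ec_numbers = r$ec_numbers)
    }),
    genes = model$genes,
    objective = model$objective,
    annotations = model$annotations
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
}

format_equation <- function(st) {
  side <- function(v) {
    if (length(v) == 0L) return("")
    paste(sprintf("%.15g %s", abs(unname(v)), names(v)), collapse = " + ")
  }
  paste(side(st[st < 0]), "->", side(st[st > 0]))
}

parse_equation <- function(text) {
  halves <- strsplit(text, "<->|<=>|->", perl = TRUE)[[1L]]
  if (length(halves) > 2L) stop("bad equation: ", text, call. = FALSE)
  if (length(halves) == 1L) halves <- c(halves, "")
  parse_side <- function(s, sign) {
    s <- trimws(s)
    if (!nzchar(s)) return(numeric())
    terms <- trimws(strsplit(s, "\\+")[[1L]])
    out <- numeric()
    for (tm in terms) {
      bits <- strsplit(tm, "\\s+")[[1L]]
      if (length(bits) == 2L) {
        out[bits[2L]] <- sign * as.numeric(bits[1L])
      } else if (length(bits) == 1L) {
        out[bits[1L]] <- sign
      } else stop("bad equation term: ", tm, call. = FALSE)
    }
    out
  }
  lhs <- parse_side(halves[1L], -1)
  rhs <- parse_side(halves[2L], +1)
  both <- intersect(names(lhs), names(rhs))
  st <- c(lhs, rhs[setdiff(names(rhs), both)])
  for (m in both) st[m] <- st[m] + rhs[m]
  st[st != 0]
}

read_model_tsv <- function(path) {
  mf <- file.path(path, "metabolites.tsv")
  rf <- file.path(path, "reactions.tsv")
  if (!file.exists(mf) || !file.exists(rf)) {
    stop("TSV model directory must contain metabolites.tsv and reactions.tsv",
         call. = FALSE)
  }
  mets <- utils::read.delim(mf, stringsAsFactors = FALSE,
                            na.strings = c("NA", ""))
  mets$charge <- suppressWarnings(as.integer(mets$charge))
  rtab <- utils::read.delim(rf, stringsAsFactors = FALSE,
                            na.strings = NULL)
  rxns <- lapply(seq_len(nrow(rtab)), function(i) {
    r <- rtab[i, ]
    ec <- trimws(strsplit(r$ec_numbers, ",")[[1L]])
    list(id = r$id, name = r$name,
         stoichiometry = parse_equation(r$equation),
         lower_bound = as.numeric(r$lower_bound),
         upper_bound = as.numeric(r$upper_bound),
         gpr = r$gpr, subsystem = r$subsystem,
         ec_numbers = ec[nzchar(ec)])
  })
  meta <- file.path(path, "model.tsv")
  id <- "model"; objective <- NULL
  if (file.exists(meta)) {
    kv <- utils::read.delim(meta, stringsAsFactors = FALSE, header = FALSE)
    id <- kv$V2[kv$V1 == "id"][1L]
    objective <- kv$V2[kv$V1 == "objective"][1L]
    genes <- kv$V2[kv$V1 == "genes"][1L]
    genes <- if (is.na(genes)) character() else strsplit(genes, ",")[[1L]]
  } else {
    genes <- character()
  }
  if (length(genes) == 0L) {
    genes <- sort(unique(unlist(lapply(rxns, function(r) {
      gpr_genes(parse_gpr(r$gpr))
    }))))
  }
  new_model(id = id, metabolites = mets, reactions = rxns, genes = genes,
            objective = objective)
}

write_model_tsv <- function(model, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  utils::write.table(model$metabolites, file.path(path, "metabolites.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE, na = "NA")
  rtab <- do.call(rbind, lapply(model$reactions, function(r) {
    data.frame(id = r$id, name = r$name,
               equation = format_equation(r$stoichiometry),
               lower_bound = r$lower_bound, upper_bound = r$upper_bound,
               gpr = r$gpr, subsystem = r$subsystem,
               ec_numbers = paste(r$ec_numbers, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rtab, file.path(path, "reactions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- data.frame(
    V1 = c("id", "objective", "genes"),
    V2 = c(model$id,
           if (is.null(model$objective)) "" else model$objective,
           paste(model$genes, collapse = ",")))
  utils::write.table(meta, file.path(path, "model.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
}

sbml_attr <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- which(names(at) == name | grepl(paste0(":", name, "$"), names(at)))
  if (length(hit) == 0L) NA_character_ else unname(at[hit[1L]])
}

sbml_gpr_text <- function(assoc_node) {
  nm <- xml2::xml_name(assoc_node)
  if (nm == "geneProductRef") {
    return(sbml_attr(assoc_node, "geneProduct"))
  }
  kids <- xml2::xml_children(assoc_node)
  parts <- vapply(kids, sbml_gpr_text, character(1L))
  op <- if (nm == "and") " and " else " or "
  paste0("(", paste(parts, collapse = op), ")")
}

read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  mets <- do.call(rbind, lapply(sp_nodes, function(s) {
    ch <- sbml_attr(s, "charge")
    data.frame(
      id = sbml_attr(s, "id"),
      name = { n <- sbml_attr(s, "name"); if (is.na(n)) sbml_attr(s, "id") else n },
      formula = sbml_attr(s, "chemicalFormula"),
      charge = if (is.na(ch)) NA_integer_ else as.integer(ch),
      compartment = sbml_attr(s, "compartment"),
      stringsAsFactors = FALSE)
  }))
  boundary <- vapply(sp_nodes, function(s) {
    identical(sbml_attr(s, "boundaryCondition"), "true")
  }, logical(1L))
  boundary_ids <- mets$id[boundary]

  pars <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  parval <- stats::setNames(
    as.numeric(vapply(pars, sbml_attr, character(1L), name = "value")),
    vapply(pars, sbml_attr, character(1L), name = "id"))

  gps <- xml2::xml_find_all(
    doc, ".//*[local-name()='listOfGeneProducts']/*[local-name()='geneProduct']")
  gene_label <- stats::setNames(
    vapply(gps, function(g) {
      lab <- sbml_attr(g, "label")
      if (is.na(lab)) sbml_attr(g, "id") else lab
    }, character(1L)),
    vapply(gps, sbml_attr, character(1L), name = "id"))

  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rxns <- lapply(rx_nodes, function(rx) {
    rid <- sbml_attr(rx, "id")
    st <- numeric()
    for (sr in xml2::xml_find_all(rx, "./listOfReactants/speciesReference")) {
      co <- as.numeric(sbml_attr(sr, "stoichiometry"))
      if (is.na(co)) co <- 1
      sp <- sbml_attr(sr, "species")
      st[sp] <- (if (sp %in% names(st)) st[sp] else 0) - co
    }
    for (sr in xml2::xml_find_all(rx, "./listOfProducts/speciesReference")) {
      co <- as.numeric(sbml_attr(sr, "stoichiometry"))
      if (is.na(co)) co <- 1
      sp <- sbml_attr(sr, "species")
      st[sp] <- (if (sp %in% names(st)) st[sp] else 0) + co
    }
    st <- st[!(names(st) %in% boundary_ids)]
    lbp <- sbml_attr(rx, "lowerFluxBound")
    ubp <- sbml_attr(rx, "upperFluxBound")
    rev <- identical(sbml_attr(rx, "reversible"), "true")
    lb <- if (!is.na(lbp) && lbp %in% names(parval)) parval[[lbp]]
          else if (rev) -1000 else 0
    ub <- if (!is.na(ubp) && ubp %in% names(parval)) parval[[ubp]] else 1000
    gpr <- ""
    ga <- xml2::xml_find_first(
      rx, "./*[local-name()='geneProductAssociation']")
    if (!inherits(ga, "xml_missing")) {
      inner <- xml2::xml_children(ga)
      if (length(inner) > 0L) {
        gpr <- sbml_gpr_text(inner[[1L]])
        for (gid in names(gene_label)) {
          gpr <- gsub(gid, gene_label[[gid]], gpr, fixed = TRUE)
        }
      }
    }
    nm <- sbml_attr(rx, "name")
    list(id = rid, name = if (is.na(nm)) rid else nm, stoichiometry = st,
         lower_bound = lb, upper_bound = ub, gpr = gpr,
         subsystem = "", ec_numbers = character())
  })

  obj_node <- xml2::xml_find_first(
    doc, ".//*[local-name()='fluxObjective']")
  objective <- if (inherits(obj_node, "xml_missing")) NULL
    else sbml_attr(obj_node, "reaction")
  model_node <- xml2::xml_find_first(doc, ".//model")
  mid <- sbml_attr(model_node, "id")
  genes <- sort(unique(unname(gene_label)))
  new_model(id = if (is.na(mid)) "sbml_model" else mid,
            metabolites = mets, reactions = rxns, genes = genes,
            objective = objective)
}
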