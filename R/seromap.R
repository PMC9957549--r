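# Haplotype -> serological-allele assignment: anchoring on serologically
# fixed, haplotype-monomorphic lines; extension by co-segregation; and a
# concordance audit between DNA-defined and serology-defined genotypes.

.new_map <- function() {
  data.frame(haplotype = character(), allele = character(),
             provenance = character(), stringsAsFactors = FALSE)
}

.map_vec <- function(map) stats::setNames(map$allele, map$haplotype)

#' Anchor haplotypes to serological alleles via fixed lines
#'
#' A line that is serologically fixed for one allele and carries exactly one
#' haplotype proves that haplotype's allele (e.g. a D3-homozygous line
#' containing only CD99-H03 proves D3 = CD99-H03). Lines fixed serologically
#' but carrying two haplotypes are ambiguous and contribute nothing.
#' Conflicting anchors (one haplotype, two alleles) are a hard error listing
#' the evidence.
#'
#' @param profiles Line profiles (`line_id`, `status`, list-column
#'   `alleles`).
#' @param line_haplotypes Named list: line id -> character vector of
#'   haplotype labels observed in that line.
#' @return Map data frame `haplotype`, `allele`, `provenance = "anchor"`.
#' @export
anchor_map <- function(profiles, line_haplotypes) {
  map <- .new_map()
  evidence <- list()
  for (i in seq_len(nrow(profiles))) {
    if (profiles$status[i] != "fixed") next
    al <- profiles$alleles[[i]]
    if (length(al) != 1L || is.na(al)) next
    haps <- unique(line_haplotypes[[profiles$line_id[i]]])
    if (length(haps) != 1L) next   # haplotype-polymorphic: ambiguous
    hit <- map$haplotype == haps
    if (any(hit)) {
      if (map$allele[hit] != al) {
        stop("mapping error: conflicting anchors for ", haps, ": ",
             map$allele[hit], " (", evidence[[haps]], ") vs ", al,
             " (line ", profiles$line_id[i], ")")
      }
    } else {
      map <- rbind(map, data.frame(haplotype = haps, allele = al,
                                   provenance = "anchor",
                                   stringsAsFactors = FALSE))
      evidence[[haps]] <- paste("line", profiles$line_id[i])
    }
  }
  map
}

# unordered translated pair for one individual
.translate <- function(h1, h2, mv) sort(c(mv[[h1]], mv[[h2]]))

# does the translated pair agree with a serology record?
.record_agrees <- function(pair, allele1, allele2, partial) {
  obs <- c(allele1, allele2)
  obs <- obs[!is.na(obs)]
  if (isTRUE(partial)) {
    return(all(pair %in% obs))  # any compatible completion matches
  }
  if (length(obs) == 1L) obs <- c(obs, obs)  # single antigen = homozygous read
  identical(sort(obs), pair)
}

#' Extend a serology map by co-segregation
#'
#' Unmapped haplotypes are first inherited through protein-identity classes:
#' a haplotype in the same missense-projection class as a mapped one takes
#' that allele (provenance `"protein-class"`), since identical proteins are
#' serologically indistinguishable. Remaining unmapped haplotypes present in
#' the diplotypes are assigned to unmapped serological names by brute force
#' over all injective assignments, choosing the one maximising exact
#' diplotype agreement (partial records count as agreeing when compatible).
#' A tied maximum leaves the tied haplotypes unmapped and reports the tie;
#' anchored entries are never overwritten.
#'
#' @param map Map data frame from [anchor_map()].
#' @param diplotypes Data frame `individual_id`, `hap1`, `hap2`.
#' @param serology Data frame `individual_id`, `allele1`, `allele2`,
#'   `partial`.
#' @param classes Optional named vector haplotype label -> protein-class id
#'   (e.g. built from [protein_classes()]); enables class inheritance.
#' @return Extended map with new rows (provenance `"protein-class"` or
#'   `"cosegregation"`) and attributes `tie` (logical) and `tie_report`.
#' @export
cosegregation_extend <- function(map, diplotypes, serology, classes = NULL) {
  serology <- serology[match(diplotypes$individual_id,
                             serology$individual_id), ]
  present <- unique(c(diplotypes$hap1, diplotypes$hap2))

  if (!is.null(classes)) {
    for (h in setdiff(present, map$haplotype)) {
      if (!h %in% names(classes)) next
      mates <- map$haplotype[map$haplotype %in%
                               names(classes)[classes == classes[[h]]]]
      if (length(mates)) {
        map <- rbind(map, data.frame(haplotype = h,
                                     allele = map$allele[map$haplotype ==
                                                           mates[1]][1],
                                     provenance = "protein-class",
                                     stringsAsFactors = FALSE))
      }
    }
  }

  unmapped_h <- setdiff(present, map$haplotype)
  seen_alleles <- unique(stats::na.omit(c(serology$allele1,
                                          serology$allele2)))
  unmapped_a <- setdiff(seen_alleles, map$allele)
  attr(map, "tie") <- FALSE
  if (!length(unmapped_h) || !length(unmapped_a)) {
    if (length(unmapped_h)) {
      message("cosegregation_extend: no unmapped serological name for ",
              paste(unmapped_h, collapse = ", "), "; left unmapped")
    }
    return(map)
  }

  k <- length(unmapped_h)
  if (k > length(unmapped_a)) {
    # assign only as many haplotypes as there are names; enumerate subsets
    subsets <- utils::combn(unmapped_h, length(unmapped_a), simplify = FALSE)
  } else {
    subsets <- list(unmapped_h)
  }
  perm <- function(v) {
    if (length(v) <= 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i) {
      lapply(perm(v[-i]), function(p) c(v[i], p))
    }))
  }
  score_assignment <- function(mv) {
    ok <- diplotypes$hap1 %in% names(mv) & diplotypes$hap2 %in% names(mv)
    sum(vapply(which(ok), function(i) {
      pair <- .translate(diplotypes$hap1[i], diplotypes$hap2[i], mv)
      .record_agrees(pair, serology$allele1[i], serology$allele2[i],
                     serology$partial[i])
    }, logical(1)))
  }
  best_score <- -1L; best <- list(); base_mv <- .map_vec(map)
  for (hs in subsets) {
    for (as_ in perm(unmapped_a)[] ) {
      if (length(as_) < length(hs)) next
      mv <- c(base_mv, stats::setNames(as_[seq_along(hs)], hs))
      s <- score_assignment(mv)
      if (s > best_score) { best_score <- s; best <- list(list(h = hs, a = as_[seq_along(hs)])) }
      else if (s == best_score) best[[length(best) + 1L]] <- list(h = hs, a = as_[seq_along(hs)])
    }
  }
  # keep only assignments identical across all ties; tied haplotypes stay
  # unmapped
  if (length(best) == 1L) {
    b <- best[[1]]
    add <- data.frame(haplotype = b$h, allele = b$a,
                      provenance = "cosegregation", stringsAsFactors = FALSE)
    map <- rbind(map, add)
    attr(map, "tie") <- FALSE
  } else {
    per_h <- lapply(unmapped_h, function(h) {
      unique(vapply(best, function(b) {
        i <- match(h, b$h); if (is.na(i)) NA_character_ else b$a[i]
      }, character(1)))
    })
    names(per_h) <- unmapped_h
    stable <- vapply(per_h, function(x) length(x) == 1L && !is.na(x),
                     logical(1))
    if (any(stable)) {
      add <- data.frame(haplotype = unmapped_h[stable],
                        allele = vapply(per_h[stable], `[[`, "", 1),
                        provenance = "cosegregation",
                        stringsAsFactors = FALSE)
      map <- rbind(map, add)
    }
    attr(map, "tie") <- TRUE
    attr(map, "tie_report") <- per_h[!stable]
    message("cosegregation_extend: tied evidence for ",
            paste(unmapped_h[!stable], collapse = ", "), "; left unmapped")
  }
  map
}

#' Audit concordance between SNP-derived and serological genotypes
#'
#' Each individual's diplotype is translated through the map and compared,
#' as an unordered pair, with the serology record. Disagreements are
#' classified as:
#'
#' * `second_allele_missed` - the serology names are a strict subset of the
#'   translated pair (one antigen not identified);
#' * `second_allele_wrong` - exactly one shared allele;
#' * `homozygote_misidentified` - translated pair homozygous but serology
#'   heterozygous or disjoint;
#' * `both_alleles_wrong` - translated pair heterozygous, no shared allele.
#'
#' Partial ("X and/or Y") records agree when the translated pair is
#' compatible with any completion; those agreements are tallied separately
#' in `n_partial_agree`.
#'
#' @param map Map data frame (`haplotype`, `allele`).
#' @param diplotypes Data frame `individual_id`, `line_id` (optional),
#'   `hap1`, `hap2`.
#' @param serology Data frame `individual_id`, `allele1`, `allele2`,
#'   `partial`.
#' @return List `n_total`, `n_agree`, `fraction`, `classes` (named counts),
#'   `n_partial_agree`, `per_line` (data frame, when line ids are present).
#' @export
concordance <- function(map, diplotypes, serology) {
  mv <- .map_vec(map)
  miss <- setdiff(unique(c(diplotypes$hap1, diplotypes$hap2)), names(mv))
  if (length(miss)) {
    who <- diplotypes$individual_id[diplotypes$hap1 %in% miss |
                                      diplotypes$hap2 %in% miss][1]
    stop("mapping error: unmapped haplotype ", miss[1],
         " (e.g. individual ", who, ")")
  }
  serology <- serology[match(diplotypes$individual_id,
                             serology$individual_id), ]
  classes <- c(second_allele_missed = 0L, second_allele_wrong = 0L,
               homozygote_misidentified = 0L, both_alleles_wrong = 0L)
  n_agree <- 0L; n_partial_agree <- 0L
  line <- if ("line_id" %in% colnames(diplotypes)) diplotypes$line_id else
    rep("all", nrow(diplotypes))
  per_line <- list()
  for (i in seq_len(nrow(diplotypes))) {
    pair <- .translate(diplotypes$hap1[i], diplotypes$hap2[i], mv)
    a1 <- serology$allele1[i]; a2 <- serology$allele2[i]
    partial <- isTRUE(serology$partial[i])
    agree <- .record_agrees(pair, a1, a2, partial)
    cls <- NA_character_
    if (agree) {
      n_agree <- n_agree + 1L
      if (partial) n_partial_agree <- n_partial_agree + 1L
    } else {
      obs <- c(a1, a2); obs <- obs[!is.na(obs)]
      shared <- length(intersect(unique(obs), unique(pair)))
      if (pair[1] == pair[2]) {
        cls <- "homozygote_misidentified"
      } else if (length(obs) == 1L && obs %in% pair) {
        cls <- "second_allele_missed"      # strict subset: one antigen seen
      } else if (shared == 1L) {
        cls <- "second_allele_wrong"
      } else {
        cls <- "both_alleles_wrong"
      }
      classes[cls] <- classes[cls] + 1L
    }
    key <- line[i]
    if (is.null(per_line[[key]])) per_line[[key]] <- c(0L, 0L)
    per_line[[key]] <- per_line[[key]] + c(1L, as.integer(agree))
  }
  pl <- data.frame(line_id = names(per_line),
                   n = vapply(per_line, `[`, 0L, 1),
                   n_agree = vapply(per_line, `[`, 0L, 2),
                   stringsAsFactors = FALSE)
  pl$fraction <- pl$n_agree / pl$n
  rownames(pl) <- NULL
  list(n_total = nrow(diplotypes), n_agree = n_agree,
       fraction = n_agree / nrow(diplotypes), classes = classes,
       n_partial_agree = n_partial_agree, per_line = pl)
}
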