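test_that("category tags parse from trailing bracketed suffixes", {
  expect_equal(parse_category_tag("Famotidine [Chemical/Ingredient]"),
               data.table::data.table(base_name = "Famotidine",
                                      category = "CHEMICAL_INGREDIENT"))
  expect_equal(parse_category_tag("Mesna")$category, "NONE")
  expect_equal(parse_category_tag("Mesna")$base_name, "Mesna")
  expect_equal(parse_category_tag("Aminoglycosides [Chemical/Ingredient]")$base_name,
               "Aminoglycosides")
  expect_equal(parse_category_tag("Androgen Receptor Inhibitor [EPC]")$category,
               "EPC")
  # unknown tag, wrong case, inner-whitespace trimming
  expect_equal(parse_category_tag("X [Disease/Finding]")$category, "NONE")
  expect_equal(parse_category_tag("X [epc]")$category, "NONE")
  expect_equal(parse_category_tag("X [ VA Product ]")$category, "VA_PRODUCT")
  expect_error(parse_category_tag(""), "non-empty")
})

test_that("tag parsing is a left inverse of tag construction", {
  bases <- c("Mesna", "Alpha Beta", "X-2 (complex)", "A.B")
  tags <- c("EPC", "Chemical/Ingredient", "PE", "MoA", "VA Product")
  for (b in bases) for (t in tags) {
    got <- parse_category_tag(paste0(b, " [", t, "]"))
    expect_equal(got$base_name, b)
    expect_equal(unname(c(EPC = "EPC", `Chemical/Ingredient` = "CHEMICAL_INGREDIENT",
                          PE = "PE", MoA = "MOA",
                          `VA Product` = "VA_PRODUCT")[t]),
                 got$category)
  }
})

test_that("tabular NDF-RT files load with categories, roles and parents", {
  fx <- local_fixture(fixture_spec(n_spl = 5, n_epc = 5, n_chem = 7,
                                   n_untagged = 2, seed = 9))
  store <- load_ndfrt(file.path(fx$dir, "ndfrt.tsv"), "tabular")
  tab <- table(store$concepts$category)
  expect_equal(unname(tab[["EPC"]]), 5L)
  expect_equal(unname(tab[["CHEMICAL_INGREDIENT"]]), 7L)
  expect_equal(unname(tab[["NONE"]]), 2L)        # untagged parents
  expect_equal(unname(tab[["VA_PRODUCT"]]), 10L + 2L)  # pool + children
  expect_equal(nrow(store$parents), 2L)          # child -> parent links
  expect_true(all(store$roles$role == "has_Chemical_Structure"))
  expect_false(anyDuplicated(store$concepts$nui) > 0)
})

test_that("an empty file yields an empty store; dangling links warn", {
  f <- withr::local_tempfile()
  writeLines(character(0), f)
  expect_equal(nrow(load_ndfrt(f, "tabular")$concepts), 0L)
  writeLines(c("N1\tA [EPC]\t\t\t", "N1\t\thas_PE\tN999\t"), f)
  expect_warning(store <- load_ndfrt(f, "tabular"), "dangling")
  expect_equal(store$roles$target_nui, "N999")
})

test_that("triples input with configurable predicates loads equivalently", {
  f <- withr::local_tempfile()
  p <- "http://x.org/ndfrt#"
  writeLines(c(
    sprintf('<%sN1> <%sprefName> "Alpha [EPC]" .', p, p),
    sprintf('<%sN2> <%sprefName> "Beta [Chemical/Ingredient]" .', p, p),
    sprintf('<%sN1> <%shas_Chemical_Structure> <%sN2> .', p, p, p),
    sprintf('<%sN2> <%schildOf> <%sN1> .', p, p, p)), f)
  store <- load_ndfrt(f, "triples",
                      predicates = list(preferred_name = paste0(p, "prefName"),
                                        parent = paste0(p, "childOf")))
  expect_equal(sort(store$concepts$nui), c("N1", "N2"))
  expect_equal(store$concepts$category[store$concepts$nui == "N1"], "EPC")
  expect_equal(store$roles,
               data.table::data.table(nui = "N1",
                                      role = "has_Chemical_Structure",
                                      target_nui = "N2"))
  expect_equal(store$parents$parent_nui, "N1")
})

test_that("descendants computes the transitive closure, cycle-safe", {
  f <- withr::local_tempfile()
  # chain a -> b -> c plus a leaf
  writeLines(c("a\tA\t\t\t", "b\tB\t\t\ta", "c\tC\t\t\tb",
               "leaf\tL [EPC]\t\t\t"), f)
  store <- load_ndfrt(f, "tabular")
  expect_setequal(descendants(store, "a"), c("b", "c"))
  expect_equal(descendants(store, "leaf"), character(0))
  expect_error(descendants(store, "nope"), "unknown NUI")

  # random DAG vs breadth-first brute force
  set.seed(42)
  n <- 40L
  ids <- sprintf("n%02d", seq_len(n))
  parents <- lapply(seq_len(n), function(i)
    if (i == 1L) character(0) else
      ids[sample.int(i - 1L, min(sample.int(3L, 1L), i - 1L))])
  lines <- unlist(lapply(seq_len(n), function(i)
    if (length(parents[[i]]) == 0L) sprintf("%s\tC%d\t\t\t", ids[i], i)
    else sprintf("%s\tC%d\t\t\t%s", ids[i], i, parents[[i]])))
  g <- withr::local_tempfile(); writeLines(lines, g)
  store <- load_ndfrt(g, "tabular")
  kids_of <- function(x) ids[vapply(parents, function(p) x %in% p, TRUE)]
  bfs <- function(root) {       # independent closure oracle
    seen <- character(0); q <- root
    while (length(q)) {
      k <- setdiff(unique(unlist(lapply(q, kids_of))), c(seen, root))
      seen <- c(seen, k); q <- k
    }
    sort(seen)
  }
  for (root in ids[c(1, 5, 17, 33)])
    expect_equal(sort(descendants(store, root)), bfs(root))
  # monotone: a child reachable from the root has a subset closure
  d1 <- descendants(store, ids[1])
  if (length(d1))
    expect_true(all(descendants(store, d1[1]) %in% d1))

  # cycle: traversed once, warned
  h <- withr::local_tempfile()
  writeLines(c("x\tX\t\t\ty", "y\tY\t\t\tx"), h)
  cyc <- load_ndfrt(h, "tabular")
  expect_warning(got <- descendants(cyc, "x"), "cycle")
  expect_equal(got, "y")
})
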