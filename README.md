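# herbminer

Association-rule mining of herb co-prescription patterns with an optimized
Apriori algorithm.

## The problem

Traditional Chinese medicine treats patients with *combinations* of herbs,
and a corpus of prescriptions (each a set of herbs) hides which
combinations recur beyond chance. Association-rule mining surfaces them: a
rule X → Y over a database of n transactions is scored by

- **support** = P(X ∪ Y) = count(X ∪ Y) / n
- **confidence** = P(Y | X) = count(X ∪ Y) / count(X)
- **coverage** = P(X) = count(X) / n
- **lift** = P(Y | X) / P(Y) — 1 means independence, above 1 a positive
  association
- **count** = the absolute number of transactions containing X ∪ Y

A frequent itemset is one whose support meets the minimum support
threshold; strong rules are splits of frequent itemsets whose confidence
meets the minimum confidence. Classic Apriori finds frequent itemsets
level by level but rescans the database for every candidate. `herbminer`
implements the optimized variant for sparse prescription data:

1. **Rare-item deletion** — items occurring at most once are removed to a
   fixed point, transactions emptied by the removal are dropped;
2. **Boolean incidence matrix** — one bit row per item, one bit column per
   transaction; the support of an itemset is the popcount of the AND of
   its rows, so counting never rescans the database;
3. **Row/column compression** — rows of items absent from every frequent
   itemset at the current level, and columns of transactions shorter than
   the current level k, are masked out (output is provably unchanged);
4. **Index tables** — each level maps canonical itemsets to support
   counts, replacing explicit candidate lists;
5. **Trie rule generation** — frequent itemsets are loaded into a prefix
   tree so every antecedent/consequent split is scored with two lookups.

The package also ships two deliberately naive reference miners (an
exhaustive enumerator and textbook Apriori) used to verify that the
optimization changes cost, never output, plus a deterministic synthetic
prescription-corpus generator with plantable pairwise co-occurrence and an
exact contingency-fixture builder.

## Worked example

Reconstruct a 238-prescription database in which 36 prescriptions contain
both Shengshigao (raw gypsum) and Xingren (apricot kernel), 49 contain
Shengshigao and 69 Xingren in total, and mine it at minimum support 13%,
minimum confidence 60%:

```r
library(herbminer)
db  <- build_contingency_fixture(238, 49, 69, 36, "Shengshigao", "Xingren")
fit <- herb_apriori(db, min_support = 0.13, min_confidence = 0.60)
fit
#> Optimized Apriori association-rule mining
#>   238 transactions, 158 items after rare-item deletion
#>   min support 0.13 (count >= 31), min confidence 0.6
#>   3 frequent itemset(s) across 2 level(s); 1 rule(s)
fit$rules
#>           lhs     rhs   support confidence  coverage     lift count
#> 1 Shengshigao Xingren 0.1512605  0.7346939 0.2058823 2.534161    36
```

Reading the one strong rule: prescriptions containing Shengshigao also
contain Xingren 73.5% of the time (confidence 36/49); the pair occurs in
15.1% of all prescriptions (support 36/238); Shengshigao alone covers
20.6% of them (coverage 49/238); and the pairing is 2.53 times more
frequent than independence would predict (lift). The reverse rule
Xingren → Shengshigao has confidence 36/69 ≈ 52% and is filtered out.

A synthetic corpus with a realistic popularity skew:

```r
corpus <- generate_corpus(seed = 7)   # 238 prescriptions, 237 herbs
frequency_report(corpus, top_k = 5)
#>       item count  fraction
#> 1   Gancao   109 0.4579832
#> 2 Huoxiang    79 0.3319328
#> 3   Fuling    53 0.2226891
#> 4  Xingren    50 0.2100840
#> 5 Lianqiao   47 0.1974790
```

## Command line

```sh
Rscript exec/herbminer synth  --n 238 --m 237 --seed 7 --out corpus.basket
Rscript exec/herbminer mine   --input corpus.basket --min-support 0.13 \
                              --min-confidence 0.60 --out rules.csv
Rscript exec/herbminer freq   --input corpus.basket --top 20
Rscript exec/herbminer verify --input corpus.basket   # cross-check vs naive miners
```

Input formats: **basket** (one transaction per line, items
comma-separated — `A,B` / `A` / `B,C`) and **binary incidence CSV**
(header of item labels, body of 0/1 cells, one transaction per row).
`--no-row-compress` / `--no-col-compress` disable the compressions for
equivalence experiments; `--max-rhs 1` restricts rules to single-item
consequents.

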