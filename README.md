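# mir3d

**3D-genome-guided miRNA biomarker panel selection and evaluation.**

## The problem

Serum miRNA panels can separate disease cases from controls, but panels chosen
purely by per-miRNA association statistics are typically large and redundant:
many of the top-ranked miRNAs are co-regulated and carry the same information.
The spatial organization of the genome offers a principled way to de-duplicate
them. miRNA genes that sit close together in the reconstructed 3D nucleus
(e.g. within one topologically associating domain) tend to co-express, so a
panel built from a few **representatives per spatial cluster** can be much
smaller than an association-only panel while keeping its discriminative power.

`mir3d` implements that idea as a complete, reproducible pipeline:

1. **Reconstruct** a 3D genome model from a Hi-C-like contact matrix.
   Contacts are converted to target distances (`d = c^(-alpha)`, zero-contact
   pairs capped) and embedded in 3D by multi-restart minimization of the
   normalized Kruskal stress
   `sigma(X) = sqrt( sum_{i<j} (dhat_ij - d_ij)^2 / sum_{i<j} d_ij^2 )`
   (SMACOF majorization plus a BFGS polish); the best of `n_restarts`
   conformations is kept. Structures are compared by Procrustes RMSD.
2. **Profile**: standardize expression by three internal-control miRNAs, drop
   low-expression and ambiguously annotated records.
3. **Select**: place each uniquely annotated miRNA's TSS in the model,
   cluster the placed miRNAs by DBSCAN (noise points promoted to singleton
   clusters), score every miRNA by Spearman correlation with the case label,
   and allocate a fixed panel size across clusters by largest-remainder
   proportional apportionment, filling each cluster's seats by `|rho|`.
4. **Evaluate** panels by leave-one-out cross-validation with SVM
   (classification and regression) and k-NN models, reporting accuracy,
   precision, recall, F1, AUPR and Mann-Whitney AUC.

Real cohorts and Hi-C maps at this scale are access controlled, so the package
includes a synthetic-data generator (`simulate_dataset()`) that plants a
spatially clustered differential signal with known ground truth; the whole
pipeline is validated against it. See the methods vignette
(`vignettes/mir3d-methods.Rmd`) for the model, parameter choices, and
limitations.

## Worked example

```r
library(mir3d)
options(mir3d.quiet = TRUE)
man <- run_pipeline(default_config(seed = 1), outdir = "run1")
grid <- read.csv(file.path(man$outdir, "metrics.csv"))
print(grid[, c("panel", "family", "n_features", "accuracy", "f1", "auc")],
      digits = 3)
```

Output (about two minutes on one CPU; 200 samples, 259 post-filter miRNAs):

```
        panel         family n_features accuracy    f1   auc
1         all            svc        259    0.980 0.980 0.997
2         all     svr_linear        259    0.930 0.928 0.986
3         all        svr_rbf        259    0.980 0.980 0.997
4         all knn_regression        259    0.795 0.773 0.866
5     top_scc            svc         36    0.970 0.971 0.998
6     top_scc     svr_linear         36    0.975 0.975 0.998
7     top_scc        svr_rbf         36    0.970 0.971 0.998
8     top_scc knn_regression         36    0.880 0.871 0.934
9  overlap_3d            svc         21    0.970 0.970 0.995
10 overlap_3d     svr_linear         21    0.965 0.964 0.997
11 overlap_3d        svr_rbf         21    0.980 0.980 0.995
12 overlap_3d knn_regression         21    0.875 0.869 0.936
13 cluster_3d            svc         20    0.975 0.975 0.994
14 cluster_3d     svr_linear         20    0.970 0.969 0.997
15 cluster_3d        svr_rbf         20    0.980 0.980 0.995
16 cluster_3d knn_regression         20    0.870 0.863 0.931
```

The headline result: the 20-miRNA `cluster_3d` panel (DBSCAN clusters with
proportional representatives) matches the 259-feature `all` panel (SVC AUC
0.994 vs 0.997) — *fewer but similarly discriminatory* features — while a
size-matched random panel reaches only AUC 0.78 at the same seed. On this
seed the `cluster_3d` panel recovers all 20 planted informative miRNAs.

Every artifact of the run (expression, contacts, reconstructed coordinates,
clustering, panels, predictions, ROC/PR curves, md5 manifest) is written to
`outdir`; rerunning with the same config and seed reproduces every file byte
for byte. Stages can also be run one at a time:
`run_pipeline(cfg, stages = "reconstruct", outdir = "run1")`.

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "mir3d.R", package = "mir3d"))')" \
  run-all --seed 1 --outdir run1
```

## License

MIT (see `LICENSE`).
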