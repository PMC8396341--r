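"""Embedding + density clustering helper invoked by the R package.

Reads a headerless CSV matrix (one observation per row), projects it with
UMAP to `--dim` dimensions, clusters the projection with HDBSCAN, produces
an independent 2-D UMAP projection for display, and writes a CSV
`label,x2d,y2d` plus a JSON summary on stdout.
"""
import argparse
import json
import sys

import numpy as np


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("--input", required=True)
    ap.add_argument("--output", required=True)
    ap.add_argument("--metric", default="euclidean",
                    choices=["euclidean", "manhattan", "cosine"])
    ap.add_argument("--dim", type=int, default=4)
    ap.add_argument("--neighbors", type=int, default=25)
    ap.add_argument("--min-dist", type=float, default=0.0)
    ap.add_argument("--min-cluster-size", type=int, default=5)
    ap.add_argument("--min-samples", type=int, default=16)
    ap.add_argument("--seed", type=int, default=0)
    args = ap.parse_args()

    import umap
    from sklearn.cluster import HDBSCAN

    x = np.loadtxt(args.input, delimiter=",", ndmin=2)
    if x.shape[0] < args.neighbors + 1:
        sys.exit("need at least neighbors+1 observations")

    emb = umap.UMAP(n_components=args.dim, n_neighbors=args.neighbors,
                    min_dist=args.min_dist, metric=args.metric,
                    random_state=args.seed, n_jobs=1).fit_transform(x)
    labels = HDBSCAN(min_cluster_size=args.min_cluster_size,
                     min_samples=args.min_samples).fit_predict(emb)
    view = umap.UMAP(n_components=2, n_neighbors=args.neighbors,
                     min_dist=args.min_dist, metric=args.metric,
                     random_state=args.seed + 1, n_jobs=1).fit_transform(x)

    out = np.column_stack([labels, view])
    np.savetxt(args.output, out, delimiter=",", fmt="%.10g",
               header="label,x2d,y2d", comments="")
    ncl = int(len(set(labels.tolist()) - {-1}))
    print(json.dumps({"n_clusters": ncl,
                      "n_noise": int(np.sum(labels == -1)),
                      "n": int(x.shape[0])}))


if __name__ == "__main__":
    main()
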