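"""Tree-ensemble Gini-importance bridge.

Reads a cells-by-genes CSV matrix and a label CSV, fits a random forest or
extra-trees classifier (Gini purity, sqrt feature subsets), and writes the
per-gene feature importances, one per line.
"""
import sys

import numpy as np
from sklearn.ensemble import ExtraTreesClassifier, RandomForestClassifier


def main() -> None:
    xpath, ypath, outpath, method, ntrees, seed = sys.argv[1:7]
    X = np.loadtxt(xpath, delimiter=",", ndmin=2)
    y = np.loadtxt(ypath, delimiter=",")
    cls = RandomForestClassifier if method == "rf" else ExtraTreesClassifier
    clf = cls(
        n_estimators=int(ntrees),
        max_features="sqrt",
        criterion="gini",
        random_state=int(seed),
        n_jobs=1,
    )
    clf.fit(X, y)
    np.savetxt(outpath, clf.feature_importances_)


if __name__ == "__main__":
    main()
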