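#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 8-connected component labeling by iterative (stack-based) flood fill.
// Labels are assigned in row-major order of each component's first pixel,
// i.e. scanning the image row by row, left to right.
// [[Rcpp::export(name = ".label_cc8")]]
IntegerMatrix label_cc8(LogicalMatrix mask) {
    const int nr = mask.nrow(), nc = mask.ncol();
    IntegerMatrix lab(nr, nc);
    std::vector<int> stack;
    int next = 0;
    static const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
    static const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
    for (int r = 0; r < nr; ++r) {
        for (int c = 0; c < nc; ++c) {
            if (!mask(r, c) || lab(r, c) != 0) continue;
            ++next;
            lab(r, c) = next;
            stack.clear();
            stack.push_back(r + c * nr);
            while (!stack.empty()) {
                int idx = stack.back();
                stack.pop_back();
                int pr = idx % nr, pc = idx / nr;
                for (int k = 0; k < 8; ++k) {
                    int qr = pr + dr[k], qc = pc + dc[k];
                    if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
                    if (mask(qr, qc) && lab(qr, qc) == 0) {
                        lab(qr, qc) = next;
                        stack.push_back(qr + qc * nr);
                    }
                }
            }
        }
    }
    return lab;
}
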