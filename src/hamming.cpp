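#include <Rcpp.h>
using namespace Rcpp;

// A char matches only if both sides are the same symbol from {A,C,G,T}.
// Anything outside that alphabet (N, ambiguity codes) is a mismatch even
// against itself, so degenerate bases never create spurious placements.
static inline bool base_match(char a, char b) {
    if (a != b) return false;
    return a == 'A' || a == 'C' || a == 'G' || a == 'T';
}

// Exhaustive ungapped scan of every read against every hairpin at every
// offset (forward strand). Keeps only placements at each read's minimal
// observed mismatch count, subject to the cap.
// [[Rcpp::export]]
DataFrame cpp_align_reads(CharacterVector reads, CharacterVector hairpins,
                          int max_mismatches) {
    int n_reads = reads.size(), n_hp = hairpins.size();
    std::vector<std::string> hp(n_hp);
    for (int j = 0; j < n_hp; ++j) hp[j] = as<std::string>(hairpins[j]);

    std::vector<int> out_read, out_hp, out_start, out_mm;

    for (int i = 0; i < n_reads; ++i) {
        std::string rd = as<std::string>(reads[i]);
        int L = rd.size();
        int best = max_mismatches + 1;
        std::vector<int> hit_hp, hit_start, hit_mm;
        for (int j = 0; j < n_hp; ++j) {
            int H = hp[j].size();
            for (int s = 0; s + L <= H; ++s) {
                int mm = 0;
                for (int k = 0; k < L; ++k) {
                    if (!base_match(rd[k], hp[j][s + k])) {
                        if (++mm > max_mismatches) break;
                    }
                }
                if (mm <= max_mismatches) {
                    if (mm < best) {
                        best = mm;
                        hit_hp.clear(); hit_start.clear(); hit_mm.clear();
                    }
                    if (mm == best) {
                        hit_hp.push_back(j + 1);
                        hit_start.push_back(s + 1);
                        hit_mm.push_back(mm);
                    }
                }
            }
        }
        for (size_t h = 0; h < hit_hp.size(); ++h) {
            out_read.push_back(i + 1);
            out_hp.push_back(hit_hp[h]);
            out_start.push_back(hit_start[h]);
            out_mm.push_back(hit_mm[h]);
        }
    }
    return DataFrame::create(_["read"] = out_read, _["hairpin"] = out_hp,
                             _["start"] = out_start,
                             _["mismatches"] = out_mm,
                             _["stringsAsFactors"] = false);
}

// Leftmost suffix-of-read / prefix-of-adapter match with Hamming mismatches
// only. Returns, per read, the 0-based insert length (= match start), or -1
// when no acceptable match exists.
// [[Rcpp::export]]
IntegerVector cpp_find_adapter(CharacterVector reads, std::string adapter,
                               int min_overlap, int max_mismatches) {
    int n = reads.size(), A = adapter.size();
    IntegerVector pos(n);
    for (int i = 0; i < n; ++i) {
        std::string rd = as<std::string>(reads[i]);
        int L = rd.size();
        int found = -1;
        for (int s = 0; s <= L - min_overlap; ++s) {
            int ov = std::min(L - s, A);
            int mm = 0;
            bool ok = true;
            for (int k = 0; k < ov; ++k) {
                if (!base_match(rd[s + k], adapter[k])) {
                    if (++mm > max_mismatches) { ok = false; break; }
                }
            }
            if (ok) { found = s; break; }
        }
        pos[i] = found;
    }
    return pos;
}
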