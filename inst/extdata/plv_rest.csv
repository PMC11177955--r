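"","SMA","PreMA_L","PreMA_R","BA_L","BA_R","AG_L","AG_R","WA_L","WA_R","SMG_L","SMG_R"
"SMA",1,0.712,0.712,0.662,0.373684210526316,0.289473684210526,0.310526315789474,0.712,0.712,0.205263157894737,0.284210526315789
"PreMA_L",0.712,1,0.712,0.215789473684211,0.315789473684211,0.368421052631579,0.378947368421053,0.712,0.712,0.336842105263158,0.639
"PreMA_R",0.712,0.712,1,0.2,0.268421052631579,0.305263157894737,0.352631578947368,0.712,0.712,0.3,0.236842105263158
"BA_L",0.662,0.215789473684211,0.2,1,0.689,0.363157894736842,0.231578947368421,0.273684210526316,0.342105263157895,0.384210526315789,0.321052631578947
"BA_R",0.373684210526316,0.315789473684211,0.268421052631579,0.689,1,0.247368421052632,0.242105263157895,0.357894736842105,0.347368421052632,0.257894736842105,0.252631578947368
"AG_L",0.289473684210526,0.368421052631579,0.305263157894737,0.363157894736842,0.247368421052632,1,0.689,0.221052631578947,0.294736842105263,0.394736842105263,0.389473684210526
"AG_R",0.310526315789474,0.378947368421053,0.352631578947368,0.231578947368421,0.242105263157895,0.689,1,0.326315789473684,0.682,0.4,0.331578947368421
"WA_L",0.712,0.712,0.712,0.273684210526316,0.357894736842105,0.221052631578947,0.326315789473684,1,0.712,0.210526315789474,0.278947368421053
"WA_R",0.712,0.712,0.712,0.342105263157895,0.347368421052632,0.294736842105263,0.682,0.712,1,0.226315789473684,0.263157894736842
"SMG_L",0.205263157894737,0.336842105263158,0.3,0.384210526315789,0.257894736842105,0.394736842105263,0.4,0.210526315789474,0.226315789473684,1,0.762
"SMG_R",0.284210526315789,0.639,0.236842105263158,0.321052631578947,0.252631578947368,0.389473684210526,0.331578947368421,0.278947368421053,0.263157894736842,0.762,1
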