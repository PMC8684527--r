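method,sharpener,rmse,pfe,mae,entropy,snr,psnr,cc,ergas
average,none, 7.99112598440844,11.65882541920237, 9.06258940841206,6.94705808348277,24.7187129988455,30.0786440565371,0.998300962943247, 6.08750333097802
minimum,none,11.30716240600426,16.75958140080031, 9.06258940841206,6.93124634191607,21.7037999503280,27.0637310080196,0.996492839727291, 8.61360325750837
dwt,none, 6.55809700027081, 9.55842258913522, 9.66203512965346,7.06266305236202,26.4353158310946,31.7952468887862,0.998857979779455, 4.99584631901919
swt,none, 5.65524432219803, 8.24358666038522, 9.29551749737728,7.05295830102109,27.7218451031929,33.0817761608844,0.999150559700343, 4.30806856456081
dwt,laplacian,15.80734145720349,22.90179863875327,27.89098266514799,7.44234630907659,18.7936958576600,24.1536269153516,0.993444073070950,12.04176282070675
dwt,unsharp, 6.62777641250220, 9.64441550027379,13.23040442306049,7.20724316531454,26.3435155688791,31.7034466265707,0.998837318906135, 5.04892690552061
dwt,lf_dft,12.36251329463467,17.96999674689640,21.14644940870419,7.31810910722429,20.9287371180806,26.2886681757722,0.995963490342300, 9.41755154494910
swt,laplacian,15.17892066114439,21.99491440322149,27.18556049096332,7.43427459764931,19.1460547318860,24.5059857895776,0.993952987234569,11.56304258819763
swt,unsharp, 5.33774910080212, 7.76858038894038,12.50723131175060,7.18976804227665,28.2237094298409,33.5836404875325,0.999245617446397, 4.06620612595225
swt,lf_dft,11.85862266729118,17.23950830926280,20.73970851678619,7.31441799273630,21.2901875439998,26.6501186016914,0.996284991916756, 9.03369626868553
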