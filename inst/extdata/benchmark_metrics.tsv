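dataset	split	method	se	sp	ppv	f_score	g_mean	auroc	aupr
human	cv	mirboost	0.803	0.988	0.887	0.843	0.891	-	-
human	cv	micropred	0.763	0.989	0.888	0.820	0.869	0.974	0.890
human	cv	deepmirgene	0.799	0.988	0.885	0.839	0.888	0.984	0.915
human	cv	dcnn_fixed	0.878	0.978	0.827	0.849	0.926	0.984	0.915
human	cv	dcnn_variable	0.835	0.985	0.868	0.851	0.907	0.985	0.922
human	cv	cnn_blstm	0.989	0.935	0.992	0.991	0.962	0.962	0.854
human	test	mirboost	0.884	0.969	0.768	0.822	0.925	-	-
human	test	micropred	0.779	0.988	0.882	0.827	0.877	0.980	0.892
human	test	deepmirgene	0.822	0.992	0.919	0.868	0.903	0.981	0.918
human	test	dcnn_fixed	0.930	0.984	0.870	0.899	0.957	0.983	0.946
human	test	dcnn_variable	0.884	0.991	0.916	0.899	0.936	0.986	0.934
human	test	cnn_blstm	0.968	0.895	0.988	0.978	0.931	0.972	0.807
cross_species	cv	mirboost	0.861	0.977	0.884	0.872	0.917	-	-
cross_species	cv	micropred	0.825	0.975	0.875	0.848	0.897	0.970	0.873
cross_species	cv	deepmirgene	0.886	0.982	0.911	0.898	0.933	0.985	0.927
cross_species	cv	dcnn_fixed	0.903	0.978	0.894	0.898	0.940	0.985	0.936
cross_species	cv	dcnn_variable	0.881	0.981	0.906	0.893	0.930	0.983	0.936
cross_species	cv	cnn_blstm	0.995	0.950	0.990	0.992	0.972	0.972	0.933
cross_species	test	mirboost	0.856	0.844	0.526	0.651	0.850	-	-
cross_species	test	micropred	0.814	0.985	0.919	0.863	0.896	0.963	0.906
cross_species	test	deepmirgene	0.900	0.983	0.913	0.906	0.940	0.984	0.955
cross_species	test	dcnn_fixed	0.904	0.982	0.910	0.907	0.942	0.983	0.951
cross_species	test	dcnn_variable	0.880	0.988	0.936	0.907	0.933	0.985	0.950
cross_species	test	cnn_blstm	0.977	0.910	0.982	0.979	0.943	0.958	0.877
new	test	mirboost	0.921	0.936	0.609	0.733	0.928	-	-
new	test	micropred	0.728	0.970	0.672	0.699	0.840	0.940	0.756
new	test	deepmirgene	0.917	0.964	0.682	0.782	0.941	0.981	0.808
new	test	dcnn_fixed	0.917	0.967	0.696	0.792	0.942	0.979	0.864
new	test	dcnn_variable	0.859	0.981	0.779	0.817	0.918	0.979	0.818
new	test	cnn_blstm	0.970	0.907	0.992	0.981	0.938	0.939	0.746
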